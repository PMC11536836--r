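#' @import methods
#' @importFrom GenomicRanges GRanges seqnames start end width strand mcols mcols<-
#'   findOverlaps pintersect reduce setdiff intersect union granges sort tileGenome
#' @importFrom IRanges IRanges ranges overlapsAny subsetByOverlaps
#' @importFrom S4Vectors queryHits subjectHits DataFrame Rle runValue
#' @importFrom GenomeInfoDb seqlevels seqlevels<- seqlengths seqlengths<- seqinfo
#'   Seqinfo keepSeqlevels seqnames<-
NULL

#' GenomeModel: the coordinate frame for copy-number analysis
#'
#' Holds the autosomal coordinate system every other component works in:
#' chromosome lengths, p/q arm boundaries, cytogenetic bands, gene positions
#' and methylation-probe annotation. Bands within a chromosome are
#' non-overlapping, sorted and tile the full chromosome; each band lies in
#' exactly one arm. All coordinates are 0-based half-open internally
#' (UCSC convention); GRanges slots store them 1-based as usual for
#' Bioconductor containers, converted on load/write.
#'
#' @slot chromosomes data.frame with columns `chrom`, `length`.
#' @slot arms GRanges of chromosome arms, mcols: `arm` ("p"/"q").
#' @slot bands GRanges of cytogenetic bands, mcols: `name`, `stain`, `arm`.
#' @slot genes GRanges of genes, mcols: `gene_id` (may be empty).
#' @slot probes GRanges of methylation probes, mcols: `probe_id`,
#'   `island_category` (island/shore/shelf/open_sea), `gene_region`
#'   (tss1500/tss200/utr5/exon1/body/utr3/intergenic) (may be empty).
#' @exportClass GenomeModel
setClass("GenomeModel", representation(
  chromosomes = "data.frame",
  arms        = "GRanges",
  bands       = "GRanges",
  genes       = "GRanges",
  probes      = "GRanges"
))

setValidity("GenomeModel", function(object) {
  msg <- character()
  ch <- object@chromosomes
  if (!all(c("chrom", "length") %in% names(ch)))
    msg <- c(msg, "chromosomes must have columns 'chrom' and 'length'")
  b <- object@bands
  if (length(b)) {
    for (cn in ch$chrom) {
      bb <- b[as.character(seqnames(b)) == cn]
      if (!length(bb)) { msg <- c(msg, paste0(cn, " has no bands")); next }
      bb <- GenomicRanges::sort(bb)
      if (GenomicRanges::start(bb)[1] != 1)
        msg <- c(msg, paste0("bands on ", cn, " do not start at chromosome start"))
      L <- ch$length[match(cn, ch$chrom)]
      if (GenomicRanges::end(bb)[length(bb)] != L)
        msg <- c(msg, paste0("bands on ", cn, " do not reach chromosome end"))
      if (length(bb) > 1 &&
          any(GenomicRanges::start(bb)[-1] != GenomicRanges::end(bb)[-length(bb)] + 1))
        msg <- c(msg, paste0("bands on ", cn, " do not tile the chromosome"))
    }
    if (is.null(b$arm)) msg <- c(msg, "bands lack arm annotation")
  }
  if (length(msg)) msg else TRUE
})

#' TrueKaryotype: ground-truth allele-specific karyotype of one sample
#'
#' Produced by the synthetic-cohort generator; segments tile every autosome
#' and carry integer copies of the two parental alleles.
#'
#' @slot sampleId single sample identifier.
#' @slot purity tumor cell fraction in (0, 1].
#' @slot segments GRanges tiling the autosomes, mcols: `cnA`, `cnB`
#'   (integer allele copies, cnA >= cnB).
#' @exportClass TrueKaryotype
setClass("TrueKaryotype", representation(
  sampleId = "character",
  purity   = "numeric",
  segments = "GRanges"
))

setValidity("TrueKaryotype", function(object) {
  msg <- character()
  if (length(object@purity) != 1 || object@purity <= 0 || object@purity > 1)
    msg <- c(msg, "purity must be a single value in (0, 1]")
  s <- object@segments
  if (length(s)) {
    if (is.null(s$cnA) || is.null(s$cnB))
      msg <- c(msg, "segments must carry cnA and cnB")
    else if (any(s$cnA < 0) || any(s$cnB < 0))
      msg <- c(msg, "allele copy numbers must be >= 0")
  }
  if (length(msg)) msg else TRUE
})

#' PurityPloidyFit: fitted purity and baseline ploidy of one sample
#'
#' Result of the grid-search lattice fit over (purity, ploidy) candidates.
#' `ploidy` is the implied ploidy (length-weighted mean fitted total copy
#' number); `psi` is the grid baseline the model was centered at.
#'
#' @slot purity fitted tumor purity in (0, 1].
#' @slot ploidy implied baseline ploidy (> 0).
#' @slot psi grid ploidy of the winning candidate.
#' @slot fit length-weighted squared-distance objective at the optimum.
#' @slot bafInformed TRUE if the BAF channel entered the objective.
#' @slot lrrOffset the length-weighted mean log-ratio subtracted before
#'   fitting (the relative-signal centering).
#' @exportClass PurityPloidyFit
setClass("PurityPloidyFit", representation(
  purity      = "numeric",
  ploidy      = "numeric",
  psi         = "numeric",
  fit         = "numeric",
  bafInformed = "logical",
  lrrOffset   = "numeric"
))

setValidity("PurityPloidyFit", function(object) {
  msg <- character()
  if (object@purity <= 0 || object@purity > 1) msg <- c(msg, "purity must be in (0, 1]")
  if (object@ploidy <= 0) msg <- c(msg, "ploidy must be > 0")
  if (length(msg)) msg else TRUE
})

#' VirtualKaryotype: reconstructed integer copy-number profile of one sample
#'
#' Segments are disjoint and carry total and minor integer copy number plus
#' two CNA class encodings: `class` relative to the rounded fitted baseline
#' ploidy and `class2` relative to the diploid state (the encoding consumed
#' by band-level representations, so a 3-copy segment in a tetraploid genome
#' is `class` "loss" but `class2` "gain").
#'
#' @slot sampleId sample identifier.
#' @slot purity fitted purity.
#' @slot ploidy fitted baseline ploidy.
#' @slot segments GRanges, mcols: `totalCN`, `minorCN` (NA when the platform
#'   carries no allele information), `class`, `class2`, `nMarkers`, `lrr`,
#'   `bafDev`, `flagged`.
#' @slot source "wgs", "snp" or "consensus".
#' @slot bafInformed whether the ploidy baseline used BAF.
#' @exportClass VirtualKaryotype
setClass("VirtualKaryotype", representation(
  sampleId    = "character",
  purity      = "numeric",
  ploidy      = "numeric",
  segments    = "GRanges",
  source      = "character",
  bafInformed = "logical"
))

setValidity("VirtualKaryotype", function(object) {
  msg <- character()
  s <- object@segments
  if (length(s)) {
    need <- c("totalCN", "class", "class2")
    if (!all(need %in% names(mcols(s))))
      msg <- c(msg, "segments must carry totalCN, class and class2")
    if (!is.null(s$minorCN)) {
      bad <- !is.na(s$minorCN) & s$minorCN > s$totalCN / 2
      if (any(bad)) msg <- c(msg, "minorCN must be <= totalCN / 2")
    }
  }
  if (length(msg)) msg else TRUE
})

#' BandCnaMatrix: band-by-sample copy-number alteration matrix
#'
#' The clustering / recurrence substrate: one row per cytogenetic band
#' (genome order), one column per sample. `states` holds -1/0/+1 for
#' loss/neutral/gain under the 60%-coverage band rule; `cn` holds the
#' length-weighted rounded integer total copy number of the band.
#'
#' @slot bands GRanges of the band rows (name, arm in mcols).
#' @slot states integer matrix in {-1, 0, 1}.
#' @slot cn integer matrix of band copy number.
#' @exportClass BandCnaMatrix
setClass("BandCnaMatrix", representation(
  bands  = "GRanges",
  states = "matrix",
  cn     = "matrix"
))

setValidity("BandCnaMatrix", function(object) {
  msg <- character()
  if (length(object@bands) != nrow(object@states))
    msg <- c(msg, "states must have one row per band")
  if (!identical(dim(object@states), dim(object@cn)))
    msg <- c(msg, "states and cn must have identical dimensions")
  if (length(object@states) && !all(object@states %in% c(-1L, 0L, 1L)))
    msg <- c(msg, "states must be in {-1, 0, 1}")
  if (length(msg)) msg else TRUE
})

#' SignatureProfile: normalized 48-channel copy-number signature
#'
#' @slot values named numeric vector of length 48, L2-normalized unless all
#'   zero.
#' @slot samples sample ids aggregated into the profile.
#' @exportClass SignatureProfile
setClass("SignatureProfile", representation(
  values  = "numeric",
  samples = "character"
))

setValidity("SignatureProfile", function(object) {
  msg <- character()
  if (length(object@values) != 48L) msg <- c(msg, "profile must have 48 channels")
  if (any(object@values < 0)) msg <- c(msg, "channel values must be >= 0")
  nrm <- sqrt(sum(object@values^2))
  if (nrm > 0 && abs(nrm - 1) > 1e-6) msg <- c(msg, "profile must be L2-normalized")
  if (length(msg)) msg else TRUE
})

#' ReferenceSignatureSet: reference copy-number signature matrix
#'
#' @slot signatures numeric matrix, 48 channel rows by one column per named
#'   reference signature; columns L2-normalized on construction.
#' @exportClass ReferenceSignatureSet
setClass("ReferenceSignatureSet", representation(signatures = "matrix"))

setValidity("ReferenceSignatureSet", function(object) {
  msg <- character()
  if (nrow(object@signatures) != 48L) msg <- c(msg, "reference matrix must have 48 rows")
  if (ncol(object@signatures) > 0 && is.null(colnames(object@signatures)))
    msg <- c(msg, "reference signatures must be named")
  if (length(msg)) msg else TRUE
})

#' SyntheticCohort: simulated cohort with ground truth and emitted layers
#'
#' @slot model the GenomeModel the cohort was simulated on.
#' @slot config the CohortConfig list (echoed verbatim, including seed).
#' @slot karyotypes list of TrueKaryotype, one per sample.
#' @slot archetypes character vector of ground-truth archetype labels.
#' @slot readDepth list of per-sample binned-count data.frames
#'   (chrom, start, end, count; 0-based half-open).
#' @slot snp list of per-sample SNP tables (chrom, pos, lrr, baf).
#' @slot expression gene-by-sample count matrix.
#' @slot methylation probe-by-sample beta-value matrix.
#' @exportClass SyntheticCohort
setClass("SyntheticCohort", representation(
  model       = "GenomeModel",
  config      = "list",
  karyotypes  = "list",
  archetypes  = "character",
  readDepth   = "list",
  snp         = "list",
  expression  = "matrix",
  methylation = "matrix"
))

## ---- show methods ----------------------------------------------------------

setMethod("show", "GenomeModel", function(object) {
  cat("GenomeModel:", nrow(object@chromosomes), "autosomes,",
      length(object@bands), "bands,", length(object@arms), "arms,",
      length(object@genes), "genes,", length(object@probes), "probes\n")
  cat("  total length:", sum(object@chromosomes$length), "bp\n")
})

setMethod("show", "TrueKaryotype", function(object) {
  cat("TrueKaryotype", object@sampleId, "| purity", object@purity,
      "|", length(object@segments), "segments | implied ploidy",
      round(impliedPloidy(object), 3), "\n")
})

setMethod("show", "PurityPloidyFit", function(object) {
  cat(sprintf("PurityPloidyFit: purity %.2f, ploidy %.2f (psi %.2f), objective %.4g, BAF %s\n",
              object@purity, object@ploidy, object@psi, object@fit,
              if (object@bafInformed) "used" else "not used"))
})

setMethod("show", "VirtualKaryotype", function(object) {
  s <- object@segments
  cat(sprintf("VirtualKaryotype %s [%s]: %d segments, purity %.2f, ploidy %.2f\n",
              object@sampleId, object@source, length(s), object@purity, object@ploidy))
  if (length(s))
    cat("  CNA (vs diploid): ", sum(s$class2 == "gain"), "gains,",
        sum(s$class2 == "loss"), "losses\n")
})

setMethod("show", "BandCnaMatrix", function(object) {
  cat("BandCnaMatrix:", nrow(object@states), "bands x", ncol(object@states),
      "samples |", sum(object@states == 1L), "gain and",
      sum(object@states == -1L), "loss entries\n")
})

setMethod("show", "SignatureProfile", function(object) {
  top <- sort(object@values, decreasing = TRUE)
  top <- top[top > 0][seq_len(min(3, sum(top > 0)))]
  cat("SignatureProfile over", length(object@samples), "sample(s); top channels:",
      paste(sprintf("%s=%.2f", names(top), top), collapse = ", "), "\n")
})

setMethod("show", "SyntheticCohort", function(object) {
  cat("SyntheticCohort:", length(object@karyotypes), "samples (",
      paste(sprintf("%s=%d", names(table(object@archetypes)), table(object@archetypes)),
            collapse = ", "), ")\n")
})

## ---- accessors -------------------------------------------------------------

#' @rdname GenomeModel-class
#' @param x,object a GenomeModel
#' @export
chromosomes <- function(x) x@chromosomes

#' @rdname GenomeModel-class
#' @export
bands <- function(x) x@bands

#' @rdname GenomeModel-class
#' @export
arms <- function(x) x@arms

#' @rdname GenomeModel-class
#' @export
genes <- function(x) x@genes

#' @rdname GenomeModel-class
#' @export
probes <- function(x) x@probes

#' @rdname VirtualKaryotype-class
#' @param x a VirtualKaryotype or TrueKaryotype
#' @export
segments <- function(x) x@segments

#' @rdname VirtualKaryotype-class
#' @export
sampleId <- function(x) x@sampleId

#' @rdname VirtualKaryotype-class
#' @export
purity <- function(x) x@purity

#' @rdname VirtualKaryotype-class
#' @export
ploidy <- function(x) x@ploidy

#' @rdname BandCnaMatrix-class
#' @param x a BandCnaMatrix
#' @export
bandStates <- function(x) x@states

#' @rdname BandCnaMatrix-class
#' @export
bandCN <- function(x) x@cn

#' @rdname SignatureProfile-class
#' @param x a SignatureProfile
#' @export
channelValues <- function(x) x@values

#' @rdname SyntheticCohort-class
#' @param x a SyntheticCohort
#' @export
karyotypes <- function(x) x@karyotypes

#' @rdname SyntheticCohort-class
#' @export
archetypes <- function(x) x@archetypes

#' Implied ploidy of a karyotype
#'
#' Length-weighted mean total copy number over all segments.
#' @param x a TrueKaryotype or VirtualKaryotype
#' @return a single numeric value
#' @export
impliedPloidy <- function(x) {
  s <- x@segments
  if (!length(s)) return(NA_real_)
  tot <- if (!is.null(s$totalCN)) s$totalCN else s$cnA + s$cnB
  sum(GenomicRanges::width(s) * tot) / sum(GenomicRanges::width(s))
}
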