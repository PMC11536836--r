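## Genome model: loading the coordinate frame and interval arithmetic.
## File coordinates are 0-based half-open (UCSC dialect); GRanges slots are
## 1-based closed as usual. Conversion happens exactly once, at load/write.

AUTOSOMES <- paste0("chr", 1:22)

.asGRanges0 <- function(chrom, start0, end0, seqlengths = NULL, ...) {
  gr <- GRanges(chrom, IRanges(start = start0 + 1L, end = end0), ...)
  if (!is.null(seqlengths)) {
    seqlevels(gr) <- names(seqlengths)
    seqlengths(gr) <- seqlengths
  }
  gr
}

#' Load a UCSC-style cytoBand table into a GenomeModel
#'
#' Reads a 5-column tab-separated cytoBand file (chrom, start, end, band
#' name, Giemsa stain; 0-based half-open coordinates). Only autosomes
#' (chr1-chr22) are retained; sex chromosomes and non-canonical contigs are
#' dropped with a message. Arm boundaries are derived from the band names:
#' the p arm ends where the last p-named band ends and the q arm starts at
#' the first q-named band (acen bands belong to their named arm).
#'
#' @param source path to a cytoBand file, or a connection.
#' @return a [GenomeModel-class] with chromosomes, bands and arms populated
#'   (genes and probes empty until [addGenes()] / [addProbes()]).
#' @examples
#' f <- system.file("extdata", "cytoBands_synthetic.txt", package = "karyoscope")
#' model <- loadCytobands(f)
#' model
#' @export
loadCytobands <- function(source) {
  raw <- utils::read.table(source, sep = "\t", header = FALSE,
                           colClasses = "character", quote = "",
                           comment.char = "#", fill = TRUE)
  if (ncol(raw) != 5)
    stop("cytoBand input must have 5 columns (chrom, start, end, name, stain), got ",
         ncol(raw))
  names(raw) <- c("chrom", "start", "end", "name", "stain")
  st <- suppressWarnings(as.integer(raw$start))
  en <- suppressWarnings(as.integer(raw$end))
  bad <- which(is.na(st) | is.na(en) | en <= st | raw$chrom == "" | raw$name == "")
  if (length(bad))
    stop("malformed cytoBand row at line ", bad[1], ": ",
         paste(unlist(raw[bad[1], ]), collapse = "\t"))
  keep <- raw$chrom %in% AUTOSOMES
  nDropped <- length(unique(raw$chrom[!keep]))
  if (nDropped > 0)
    message("dropping ", nDropped,
            " non-autosomal sequence(s); analysis is limited to autosomes")
  raw <- raw[keep, , drop = FALSE]; st <- st[keep]; en <- en[keep]
  if (!nrow(raw)) stop("no autosomal bands found in input")

  o <- order(match(raw$chrom, AUTOSOMES), st)
  raw <- raw[o, , drop = FALSE]; st <- st[o]; en <- en[o]
  armChar <- substr(raw$name, 1, 1)
  if (!all(armChar %in% c("p", "q")))
    stop("band names must start with 'p' or 'q'")

  chromNames <- unique(raw$chrom)
  lens <- vapply(chromNames, function(cn) max(en[raw$chrom == cn]), integer(1))
  chromosomes <- data.frame(chrom = chromNames, length = as.numeric(lens),
                            stringsAsFactors = FALSE)
  sl <- lens; names(sl) <- chromNames

  bandsGr <- .asGRanges0(raw$chrom, st, en, seqlengths = sl,
                         name = raw$name, stain = raw$stain, arm = armChar)

  armRows <- lapply(chromNames, function(cn) {
    sel <- raw$chrom == cn
    if (!any(armChar[sel] == "q"))
      stop("chromosome ", cn, " has no q-named band")
    if (!any(armChar[sel] == "p"))
      stop("chromosome ", cn, " has no p-named band")
    pEnd <- max(en[sel & armChar == "p"])
    qStart <- min(st[sel & armChar == "q"])
    if (pEnd != qStart)
      stop("p/q bands on ", cn, " do not meet at a single centromere coordinate")
    data.frame(chrom = cn, start0 = c(0L, qStart),
               end0 = c(pEnd, max(en[sel])), arm = c("p", "q"))
  })
  armDf <- do.call(rbind, armRows)
  armsGr <- .asGRanges0(armDf$chrom, armDf$start0, armDf$end0,
                        seqlengths = sl, arm = armDf$arm)

  new("GenomeModel", chromosomes = chromosomes, arms = armsGr,
      bands = bandsGr, genes = GRanges(), probes = GRanges())
}

#' Attach a gene set to a GenomeModel
#'
#' @param model a [GenomeModel-class].
#' @param genes a BED-like data.frame (chrom, start, end, gene_id; 0-based
#'   half-open) or path to such a file (tab-separated, no header). Any gene
#'   list can be supplied; gene-density results refer to whatever set is
#'   loaded. Non-autosomal rows are dropped.
#' @return the model with `genes` populated.
#' @export
addGenes <- function(model, genes) {
  if (is.character(genes))
    genes <- utils::read.table(genes, sep = "\t", header = FALSE,
                               col.names = c("chrom", "start", "end", "gene_id"),
                               colClasses = c("character", "integer", "integer", "character"))
  genes <- genes[genes$chrom %in% model@chromosomes$chrom, , drop = FALSE]
  sl <- stats::setNames(model@chromosomes$length, model@chromosomes$chrom)
  gr <- .asGRanges0(genes$chrom, genes$start, genes$end, seqlengths = sl,
                    gene_id = genes$gene_id)
  model@genes <- GenomicRanges::sort(gr)
  validObject(model)
  model
}

#' Attach methylation-probe annotation to a GenomeModel
#'
#' @param model a [GenomeModel-class].
#' @param probes a data.frame (probe_id, chrom, pos, island_category,
#'   gene_region) or path to such a tab-separated file with header. `pos` is
#'   0-based. Categories follow the usual methylation-array annotation:
#'   island/shore/shelf/open_sea and
#'   tss1500/tss200/utr5/exon1/body/utr3/intergenic.
#' @return the model with `probes` populated.
#' @export
addProbes <- function(model, probes) {
  if (is.character(probes))
    probes <- utils::read.table(probes, sep = "\t", header = TRUE,
                                colClasses = c("character", "character",
                                               "integer", "character", "character"))
  okIsl <- c("island", "shore", "shelf", "open_sea")
  okReg <- c("tss1500", "tss200", "utr5", "exon1", "body", "utr3", "intergenic")
  if (!all(probes$island_category %in% okIsl))
    stop("unknown island_category value(s)")
  if (!all(probes$gene_region %in% okReg))
    stop("unknown gene_region value(s)")
  probes <- probes[probes$chrom %in% model@chromosomes$chrom, , drop = FALSE]
  sl <- stats::setNames(model@chromosomes$length, model@chromosomes$chrom)
  gr <- .asGRanges0(probes$chrom, probes$pos, probes$pos + 1L, seqlengths = sl,
                    probe_id = probes$probe_id,
                    island_category = probes$island_category,
                    gene_region = probes$gene_region)
  model@probes <- GenomicRanges::sort(gr)
  model
}

#' Fraction of a band covered by a segment
#'
#' Overlap length divided by band length; 0 when the two ranges are on
#' different chromosomes or disjoint. This is the quantity compared against
#' the 60% band-mapping rule.
#'
#' @param segment,band single-range GRanges.
#' @return a fraction in [0, 1].
#' @export
bandOverlapFraction <- function(segment, band) {
  stopifnot(length(segment) == 1, length(band) == 1)
  if (as.character(seqnames(segment)) != as.character(seqnames(band))) return(0)
  ov <- min(end(segment), end(band)) - max(start(segment), start(band)) + 1
  max(0, ov) / width(band)
}

#' Gene density per cytogenetic band
#'
#' Each gene is assigned to the single band containing its midpoint (a
#' partition: every gene counted exactly once); density is genes per Mb of
#' band length.
#'
#' @param model a [GenomeModel-class] with genes loaded.
#' @return numeric vector, one density per band (band name as names).
#' @export
geneDensityPerBand <- function(model) {
  b <- model@bands
  if (!length(model@genes)) stop("no genes loaded in model")
  g <- model@genes
  mid <- floor((start(g) + end(g)) / 2)
  midGr <- GRanges(seqnames(g), IRanges(mid, mid))
  hits <- findOverlaps(midGr, b)
  counts <- tabulate(subjectHits(hits), nbins = length(b))
  stats::setNames(counts / (width(b) / 1e6), b$name)
}

## ---- interval arithmetic (thin wrappers over IRanges) ---------------------

#' Interval-set operations
#'
#' Disjoint, sorted, half-open interval sets on a shared coordinate frame,
#' represented as GRanges. These are closed under union, intersection and
#' subtraction and replace ad-hoc bedtools-style merging/intersection calls.
#'
#' @param a,b GRanges (strand ignored).
#' @return a reduced (disjoint, sorted) GRanges.
#' @name intervalOps
NULL

#' @rdname intervalOps
#' @export
intervalUnion <- function(a, b = NULL) {
  x <- if (is.null(b)) a else c(granges(a), granges(b))
  reduce(GenomicRanges::sort(granges(x)), ignore.strand = TRUE)
}

#' @rdname intervalOps
#' @export
intervalIntersect <- function(a, b) {
  GenomicRanges::intersect(granges(a), granges(b), ignore.strand = TRUE)
}

#' @rdname intervalOps
#' @export
intervalSubtract <- function(a, b) {
  GenomicRanges::setdiff(granges(a), granges(b), ignore.strand = TRUE)
}

## ---- synthetic genome ------------------------------------------------------

# hg19-proportional autosome lengths (Mb), centromere position as a fraction
# of chromosome length, and approximate protein-coding gene counts; the
# scaffolding for the scaled synthetic genome.
.HG19 <- list(
  lenMb = c(249.25, 243.20, 198.02, 191.15, 180.92, 171.12, 159.14, 146.36,
            141.21, 135.53, 135.01, 133.85, 115.17, 107.35, 102.53,  90.35,
             81.20,  78.08,  59.13,  63.03,  48.13,  51.30),
  cenFrac = c(0.50, 0.38, 0.46, 0.26, 0.27, 0.36, 0.38, 0.31, 0.35, 0.30,
              0.40, 0.27, 0.16, 0.16, 0.19, 0.41, 0.30, 0.22, 0.42, 0.44,
              0.27, 0.29),
  geneCount = c(2058, 1309, 1078, 762, 876, 1048, 917, 688, 786, 733,
                1314, 1034, 327, 623, 613, 871, 1197, 276, 1473, 546,
                234, 492)
)

#' Build a scaled synthetic genome model
#'
#' Deterministically constructs an hg19-proportional autosomal genome at a
#' reduced scale: chromosome lengths and centromere positions follow the
#' hg19 proportions divided by `scale`, bands of roughly `bandLength` tile
#' each arm, genes are placed at per-chromosome densities proportional to
#' the real protein-coding gene counts, and each gene gets a panel of
#' methylation probes (promoter island/shore probes, body and intergenic
#' open-sea probes). The construction uses no random numbers, so the same
#' arguments always give byte-identical models.
#'
#' @param scale division factor applied to hg19 chromosome lengths (default
#'   35, giving a ~79 Mb genome).
#' @param bandLength target band length in bp (default 5e5).
#' @param binSize chromosome lengths are rounded to a multiple of this
#'   (default 1e4, the read-depth bin size).
#' @param genesTotal approximate total number of genes to place (default 2000).
#' @param chroms integer vector of autosome numbers to include (default 1:22).
#' @return a [GenomeModel-class] with bands, arms, genes and probes populated.
#' @export
syntheticGenomeModel <- function(scale = 35, bandLength = 5e5, binSize = 1e4,
                                 genesTotal = 2000, chroms = 1:22) {
  stopifnot(all(chroms %in% 1:22))
  lens <- round(.HG19$lenMb[chroms] * 1e6 / scale / binSize) * binSize
  cen  <- round(lens * .HG19$cenFrac[chroms] / binSize) * binSize
  cen  <- pmax(binSize, pmin(cen, lens - binSize))
  chromNames <- paste0("chr", chroms)

  bandRows <- list(); geneRows <- list(); probeRows <- list()
  gTotal <- .HG19$geneCount[chroms]
  gPer <- pmax(3L, round(genesTotal * gTotal / sum(.HG19$geneCount)))

  for (i in seq_along(chroms)) {
    cn <- chromNames[i]; L <- lens[i]; C <- cen[i]
    mkArm <- function(a, from, to) {
      n <- max(1L, round((to - from) / bandLength))
      cuts <- round(seq(from, to, length.out = n + 1))
      idx <- if (a == "p") rev(seq_len(n)) else seq_len(n)
      data.frame(chrom = cn, start0 = cuts[-length(cuts)], end0 = cuts[-1],
                 name = paste0(a, idx, if (a == "p") ".1" else ".1"),
                 stain = rep_len(c("gneg", "gpos50"), n), arm = a)
    }
    pb <- mkArm("p", 0, C); qb <- mkArm("q", C, L)
    pb$stain[nrow(pb)] <- "acen"; qb$stain[1] <- "acen"
    bandRows[[i]] <- rbind(pb, qb)

    ng <- gPer[i]
    # genes thin out along the chromosome (sub-telomeric p-end densest),
    # giving within-chromosome density structure on top of the
    # per-chromosome totals
    gs <- round(L * seq(0.02, 0.96, length.out = ng)^1.5)
    geneRows[[i]] <- data.frame(chrom = cn, start = as.integer(gs),
                                end = as.integer(gs + 5000L),
                                gene_id = sprintf("G%s_%03d", sub("chr", "", cn),
                                                  seq_len(ng)))
    # per-gene probe panel: promoter 5' probes (island/shore), body, 3'UTR,
    # intergenic open-sea; every 5th intergenic probe sits on a CpG shelf
    off <- c(-1000L, -150L, 150L, 600L, 2500L, 4500L, 8000L)
    reg <- c("tss1500", "tss200", "utr5", "exon1", "body", "utr3", "intergenic")
    isl <- c("shore", "island", "island", "island", "open_sea", "open_sea", "open_sea")
    pr <- data.frame(
      probe_id = paste0(rep(geneRows[[i]]$gene_id, each = length(off)), "_",
                        rep(reg, ng)),
      chrom = cn,
      pos = as.integer(rep(gs, each = length(off)) + rep(off, ng)),
      island_category = rep(isl, ng),
      gene_region = rep(reg, ng))
    shelf <- which(pr$gene_region == "intergenic")
    shelf <- shelf[seq_along(shelf) %% 5L == 0L]
    pr$island_category[shelf] <- "shelf"
    pr <- pr[pr$pos >= 0 & pr$pos < L, , drop = FALSE]
    probeRows[[i]] <- pr
  }

  bandDf <- do.call(rbind, bandRows)
  sl <- stats::setNames(as.numeric(lens), chromNames)
  model <- new("GenomeModel",
               chromosomes = data.frame(chrom = chromNames, length = as.numeric(lens),
                                        stringsAsFactors = FALSE),
               arms = .asGRanges0(rep(chromNames, each = 2),
                                  as.vector(rbind(0, cen)),
                                  as.vector(rbind(cen, lens)),
                                  seqlengths = sl,
                                  arm = rep(c("p", "q"), length(chroms))),
               bands = .asGRanges0(bandDf$chrom, bandDf$start0, bandDf$end0,
                                   seqlengths = sl, name = bandDf$name,
                                   stain = bandDf$stain, arm = bandDf$arm),
               genes = GRanges(), probes = GRanges())
  model <- addGenes(model, do.call(rbind, geneRows))
  model <- addProbes(model, do.call(rbind, probeRows))
  validObject(model)
  model
}

#' Write a GenomeModel's bands as a UCSC-style cytoBand file
#'
#' @param model a [GenomeModel-class].
#' @param file output path (tab-separated, 0-based half-open, no header).
#' @return the file path, invisibly.
#' @export
writeCytobands <- function(model, file) {
  b <- model@bands
  df <- data.frame(chrom = as.character(seqnames(b)), start = start(b) - 1L,
                   end = end(b), name = b$name, stain = b$stain)
  utils::write.table(df, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(file)
}

# genome-order index helper: bands sorted by chromosome then start
.genomeOrder <- function(model) {
  b <- model@bands
  order(match(as.character(seqnames(b)), model@chromosomes$chrom), start(b))
}

.autosomeLength <- function(model) sum(model@chromosomes$length)
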