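## 48-channel copy-number signature encoding and Euclidean similarity
## matching against reference signature profiles.
##
## Channel scheme: 3 homozygous-deletion size classes, then {LOH} x
## {total CN 1, 2, 3-4, 5-8, 9+} x 5 size classes, then {heterozygous} x
## {total CN 2, 3-4, 5-8, 9+} x 5 size classes = 3 + 25 + 20 = 48.

.SIG_SIZES_HD <- c("0-100kb", "100kb-1Mb", ">1Mb")
.SIG_SIZES <- c("0-100kb", "100kb-1Mb", "1-10Mb", "10-40Mb", ">40Mb")
.SIG_CN_LOH <- c("1", "2", "3-4", "5-8", "9+")
.SIG_CN_HET <- c("2", "3-4", "5-8", "9+")

#' Names of the 48 signature channels, in canonical order
#' @return character vector of length 48.
#' @export
signatureChannels <- function() {
  c(paste0("homdel:", .SIG_SIZES_HD),
    paste0("LOH:", rep(.SIG_CN_LOH, each = 5), ":", rep(.SIG_SIZES, 5)),
    paste0("het:", rep(.SIG_CN_HET, each = 5), ":", rep(.SIG_SIZES, 4)))
}

.cnClass <- function(total) {
  ifelse(total == 1, "1",
         ifelse(total == 2, "2",
                ifelse(total <= 4, "3-4", ifelse(total <= 8, "5-8", "9+"))))
}

.sizeClass <- function(len, classes = .SIG_SIZES) {
  cuts <- c(1e5, 1e6, 1e7, 4e7)[seq_len(length(classes) - 1)]
  classes[findInterval(len, cuts) + 1]
}

#' Map one segment to its signature channel
#'
#' Total function over (total, minor, length): homozygous deletion when
#' total = 0, else LOH when minor = 0, else heterozygous; copy-number class
#' by total, size class by length.
#'
#' @param total,minor integer copy numbers.
#' @param len segment length in bp.
#' @return a channel name (one of [signatureChannels()]).
#' @export
segmentChannel <- function(total, minor, len) {
  stopifnot(length(total) == length(minor), length(minor) == length(len))
  ifelse(total == 0,
         paste0("homdel:", .sizeClass(len, .SIG_SIZES_HD)),
         ifelse(minor == 0,
                paste0("LOH:", .cnClass(total), ":", .sizeClass(len)),
                paste0("het:", .cnClass(total), ":", .sizeClass(len))))
}

#' Encode a karyotype into 48 signature channel counts
#'
#' Every segment (including copy-neutral heterozygous segments, unless
#' `includeNeutral = FALSE`) is counted into exactly one channel. Segment
#' lengths can be rescaled with `lengthScale` so that calls made on a
#' scaled-down genome map to real-genome size classes.
#'
#' @param kt a [VirtualKaryotype-class] with allele-specific calls.
#' @param includeNeutral count neutral segments too.
#' @param lengthScale multiplier applied to segment lengths before size
#'   classification.
#' @return named integer vector of 48 channel counts.
#' @export
encodeSegments <- function(kt, includeNeutral = TRUE, lengthScale = 1) {
  s <- kt@segments
  if (!includeNeutral) s <- s[s$class != "neutral"]
  if (!length(s)) return(stats::setNames(integer(48), signatureChannels()))
  if (any(is.na(s$minorCN)))
    stop("signature encoding requires allele-specific calls (minorCN present)")
  chan <- segmentChannel(s$totalCN, s$minorCN, width(s) * lengthScale)
  counts <- table(factor(chan, levels = signatureChannels()))
  stats::setNames(as.integer(counts), signatureChannels())
}

#' Aggregate karyotypes into a normalized signature profile
#'
#' Channel counts are summed over samples and L2-normalized.
#'
#' @param kts list of [VirtualKaryotype-class].
#' @param ... passed to [encodeSegments()].
#' @return a [SignatureProfile-class]; an all-neutral cohort yields an
#'   all-zero profile with a warning.
#' @export
cohortProfile <- function(kts, ...) {
  counts <- Reduce(`+`, lapply(kts, encodeSegments, ...))
  nrm <- sqrt(sum(counts^2))
  vals <- if (nrm > 0) counts / nrm else {
    warning("all-zero signature profile (no segments encoded)")
    as.numeric(counts)
  }
  new("SignatureProfile", values = stats::setNames(as.numeric(vals), signatureChannels()),
      samples = vapply(kts, function(k) k@sampleId, ""))
}

.asChannelVector <- function(x) {
  v <- if (is(x, "SignatureProfile")) x@values else x
  if (length(v) != 48) stop("signature vectors must have 48 channels")
  nrm <- sqrt(sum(v^2))
  if (nrm > 0) v / nrm else v
}

#' Euclidean similarity between two signature profiles
#'
#' Both vectors are L2-normalized; similarity is `1 - d / sqrt(2)` where d
#' is the Euclidean distance (for nonnegative unit vectors d lies in
#' [0, sqrt(2)], so similarity lies in [0, 1]; 1 iff the profiles are
#' equal, 0 for disjoint-support profiles). `method = "inverse"` gives the
#' alternative `1 / (1 + d)`.
#'
#' @param a,b [SignatureProfile-class] objects or 48-vectors.
#' @param method "complement" (default) or "inverse".
#' @return similarity in [0, 1] (in (0, 1] for "inverse").
#' @export
euclideanSimilarity <- function(a, b, method = c("complement", "inverse")) {
  method <- match.arg(method)
  va <- .asChannelVector(a); vb <- .asChannelVector(b)
  d <- sqrt(sum((va - vb)^2))
  if (method == "complement") max(0, 1 - d / sqrt(2)) else 1 / (1 + d)
}

#' Load a reference signature matrix
#'
#' Reads a tab-separated matrix of 48 channel rows (channel names in the
#' first column, matching [signatureChannels()]) by named reference
#' signatures; columns are L2-normalized on load. The bundled default is a
#' synthetic two-signature fixture: a CN1-like diploid profile with mass on
#' heterozygous 2-copy channels and a CN2-like tetraploid profile with mass
#' on heterozygous 3-4-copy channels.
#'
#' @param file path to the matrix (default: bundled synthetic fixture).
#' @return a [ReferenceSignatureSet-class].
#' @export
referenceSignatures <- function(file = system.file("extdata",
                                                   "reference_cn_signatures_synthetic.tsv",
                                                   package = "karyoscope")) {
  df <- utils::read.table(file, sep = "\t", header = TRUE, row.names = 1,
                          check.names = FALSE)
  if (!identical(rownames(df), signatureChannels()))
    stop("reference matrix rows must match the 48 canonical channels in order")
  m <- as.matrix(df)
  m <- sweep(m, 2, pmax(sqrt(colSums(m^2)), 1e-12), "/")
  new("ReferenceSignatureSet", signatures = m)
}

#' Best-matching reference signature for a profile
#'
#' @param profile a [SignatureProfile-class] or 48-vector.
#' @param refSet a [ReferenceSignatureSet-class].
#' @return list with `name` and `similarity`; ties break to the first
#'   reference by column order.
#' @export
bestMatch <- function(profile, refSet) {
  m <- refSet@signatures
  if (!ncol(m)) stop("empty reference signature set")
  sims <- vapply(seq_len(ncol(m)), function(j)
    euclideanSimilarity(profile, m[, j]), 0)
  k <- which.max(sims)
  list(name = colnames(m)[k], similarity = sims[k])
}
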