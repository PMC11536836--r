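## Cohort-level recurrence (GISTIC-like G-scores with a cyclic-shift
## permutation null) and hierarchical clustering of band-level CNA
## patterns.

#' GISTIC-like recurrence scores per band
#'
#' For each band and class the G-score sums `|CN - 2|` over the samples in
#' that class. The null distribution is generated by cyclic within-genome
#' shifts of each sample's band vector (independent uniform shifts per
#' sample and permutation), which preserves each sample's alteration burden
#' and within-genome structure while destroying cross-sample alignment.
#' Each band's p-value is the fraction of the pooled genome-wide permuted
#' band scores at least as large as the observed score (with the +1
#' correction); q-values are Benjamini-Hochberg within class.
#'
#' @param bm a [BandCnaMatrix-class].
#' @param nPerm number of permutations (>= 1000 recommended).
#' @param seed RNG seed.
#' @return data.frame with band, chrom, class, frequency, G, p, q.
#' @export
gisticLikeScores <- function(bm, nPerm = 1000, seed = 1) {
  st <- bm@states; cn <- bm@cn
  B <- nrow(st); S <- ncol(st)
  if (S < 2) {
    warning("single-sample cohort: recurrence q-values set to 1")
    return(data.frame(band = rep(rownames(st), 2), chrom = rep(as.character(seqnames(bm@bands)), 2),
                      class = rep(c("gain", "loss"), each = B),
                      frequency = c(rowMeans(st == 1L), rowMeans(st == -1L)),
                      G = 0, p = 1, q = 1))
  }
  set.seed(seed)
  dev <- abs(cn - 2L)
  contrib <- list(gain = dev * (st == 1L), loss = dev * (st == -1L))
  out <- list()
  for (cls in c("gain", "loss")) {
    M <- contrib[[cls]]
    G <- rowSums(M)
    nullPool <- numeric(0)
    nullMat <- matrix(0, B, nPerm)
    for (k in seq_len(nPerm)) {
      shifts <- sample.int(B, S, replace = TRUE) - 1L
      perm <- vapply(seq_len(S), function(j) {
        sh <- shifts[j]
        if (sh == 0) M[, j] else M[c((sh + 1):B, 1:sh), j]
      }, numeric(B))
      nullMat[, k] <- rowSums(perm)
    }
    nullPool <- sort(as.numeric(nullMat))
    nGE <- length(nullPool) - findInterval(G - 1e-12, nullPool)
    p <- (nGE + 1) / (length(nullPool) + 1)
    q <- stats::p.adjust(p, method = "BH")
    out[[cls]] <- data.frame(band = rownames(st),
                             chrom = as.character(seqnames(bm@bands)),
                             class = cls,
                             frequency = rowMeans(st == (if (cls == "gain") 1L else -1L)),
                             G = G, p = p, q = q)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

# binary feature encoding: one gain and one loss indicator per band
.binaryFeatures <- function(bm) {
  X <- cbind(t(bm@states == 1L), t(bm@states == -1L)) * 1
  colnames(X) <- c(paste0(rownames(bm@states), "_gain"),
                   paste0(rownames(bm@states), "_loss"))
  X
}

# asymmetric binary (Jaccard) distance with the two-empty-samples = 0
# convention; cosine distance with the same convention for zero vectors
.cnaDistance <- function(X, distance) {
  n <- nrow(X)
  if (distance == "binary") {
    d <- stats::dist(X, method = "binary")
    d[is.na(d)] <- 0
    return(d)
  }
  nrm <- sqrt(rowSums(X^2))
  sim <- tcrossprod(X) / outer(pmax(nrm, 1e-12), pmax(nrm, 1e-12))
  d <- 1 - sim
  zero <- nrm == 0
  d[zero, ] <- 1; d[, zero] <- 1
  d[zero, zero] <- 0
  diag(d) <- 0
  stats::as.dist(d)
}

#' Hierarchically cluster samples on band-level CNA patterns
#'
#' Samples are encoded as binary vectors over band-by-class features
#' (gain and loss indicators per band). Distances are either the asymmetric
#' binary (Jaccard) distance — discordant features over features present in
#' at least one of the two samples, with distance 0 between two all-neutral
#' samples by convention — or cosine distance. Agglomeration is Ward on
#' squared dissimilarities (`hclust` method "ward.D2").
#'
#' @param bm a [BandCnaMatrix-class] (>= 2 samples).
#' @param distance "binary" or "cosine".
#' @return an `hclust` tree with sample-id labels.
#' @export
clusterSamples <- function(bm, distance = c("binary", "cosine")) {
  distance <- match.arg(distance)
  if (ncol(bm@states) < 2) stop("clustering needs at least 2 samples")
  X <- .binaryFeatures(bm)
  d <- .cnaDistance(X, distance)
  stats::hclust(d, method = "ward.D2")
}

#' Cut a cluster tree into k groups
#'
#' Standard tree cut with labels 1..k renumbered in order of first sample
#' occurrence, so labelings are stable across runs.
#'
#' @param tree an `hclust` object.
#' @param k number of clusters.
#' @return integer vector of cluster labels named by sample.
#' @export
cutClusters <- function(tree, k) {
  raw <- stats::cutree(tree, k = k)
  lab <- match(raw, unique(raw))
  stats::setNames(lab, names(raw))
}

#' Export a cluster tree as Newick
#'
#' @param tree an `hclust` object.
#' @param file output path.
#' @return the path, invisibly.
#' @export
writeNewick <- function(tree, file) {
  ape::write.tree(ape::as.phylo(tree), file = file)
  invisible(file)
}
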