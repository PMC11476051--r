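#' VanRaden genomic relationship matrix
#'
#' \eqn{G = Z Z' / (2 \sum_i P_i (1 - P_i))} where Z holds 0/1/2 alt-allele
#' dosages centered by twice the sample allele frequency. Missing calls are
#' imputed to \eqn{2 P_i} (they contribute zero after centering, the
#' standard GCTA/VanRaden convention). Monomorphic markers carry no
#' information and are dropped with a warning.
#'
#' @param genotypes a [GenotypeData-class] object or markers x samples call
#'   matrix.
#' @param allele_freq optional per-marker alt-allele frequencies to center
#'   with (e.g. base-population frequencies); defaults to the sample
#'   frequencies.
#' @return n x n symmetric matrix with sample ids as dimnames.
#' @export
vanRadenGRM <- function(genotypes, allele_freq = NULL) {
  m <- if (methods::is(genotypes, "GenotypeData")) genoCalls(genotypes)
       else genotypes
  p <- if (is.null(allele_freq)) altFreq(m) else allele_freq
  stopifnot(length(p) == nrow(m))
  mono <- is.na(p) | p <= 0 | p >= 1
  if (any(mono)) {
    warning(sum(mono), " monomorphic marker(s) dropped from the G matrix")
    m <- m[!mono, , drop = FALSE]
    p <- p[!mono]
  }
  if (!nrow(m)) stop("no polymorphic markers")
  z <- sweep(m, 1, 2 * p, "-")
  z[is.na(z)] <- 0
  denom <- 2 * sum(p * (1 - p))
  G <- crossprod(z) / denom
  dimnames(G) <- list(colnames(m), colnames(m))
  G
}

#' Identity-by-state genetic distance matrix
#'
#' For each sample pair, over markers non-missing in both: IBS2 counts loci
#' with identical genotypes, IBS1 loci sharing exactly one allele (a 0/1 or
#' 1/2 genotype pair), IBS0 loci with opposite homozygotes. The similarity
#' is \eqn{D_{ST} = (0.5\,IBS1 + IBS2)/N} and the distance
#' \eqn{D = 1 - D_{ST}}.
#'
#' @param genotypes a [GenotypeData-class] object or markers x samples call
#'   matrix.
#' @return list with `D` (n x n distance matrix) and `counts` (data.frame of
#'   per-pair `ibs0`, `ibs1`, `ibs2`, `n_compared`).
#' @export
ibsDistance <- function(genotypes) {
  m <- if (methods::is(genotypes, "GenotypeData")) genoCalls(genotypes)
       else genotypes
  n <- ncol(m)
  ids <- colnames(m)
  if (is.null(ids)) ids <- paste0("S", seq_len(n))
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  rows <- vector("list", n * (n - 1) / 2)
  r <- 0
  for (i in seq_len(n - 1)) {
    a <- m[, i]
    for (j in seq((i + 1), n)) {
      b <- m[, j]
      ok <- !is.na(a) & !is.na(b)
      N <- sum(ok)
      if (N == 0)
        stop("samples ", ids[i], " and ", ids[j],
             " share no comparable loci")
      dd <- abs(a[ok] - b[ok])
      ibs2 <- sum(dd == 0); ibs1 <- sum(dd == 1); ibs0 <- N - ibs1 - ibs2
      dist <- 1 - (0.5 * ibs1 + ibs2) / N
      D[i, j] <- D[j, i] <- dist
      r <- r + 1
      rows[[r]] <- data.frame(sample1 = ids[i], sample2 = ids[j],
                              ibs0 = ibs0, ibs1 = ibs1, ibs2 = ibs2,
                              n_compared = N, distance = dist)
    }
  }
  list(D = D, counts = do.call(rbind, rows))
}

#' Principal component analysis of a genomic relationship matrix
#'
#' Eigendecomposition of G; component scores are eigenvectors scaled by the
#' square root of their (non-negative) eigenvalues, and explained fractions
#' are \eqn{\lambda_i / \sum_j \max(\lambda_j, 0)}. For determinism across
#' linear-algebra backends, each eigenvector is oriented so its
#' largest-magnitude entry is positive.
#'
#' @param G symmetric relationship matrix.
#' @param k number of components to return.
#' @return list with `eigenvalues` (all, descending), `scores` (n x k),
#'   `explained` (length k).
#' @export
grmPCA <- function(G, k = 2) {
  stopifnot(isSymmetric(unname(G), tol = 1e-8))
  n <- nrow(G)
  if (k > n) stop("k cannot exceed the number of individuals")
  e <- eigen((G + t(G)) / 2, symmetric = TRUE)
  pos_total <- sum(pmax(e$values, 0))
  vec <- e$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    top <- which.max(abs(vec[, j]))
    if (vec[top, j] < 0) vec[, j] <- -vec[, j]
  }
  scores <- sweep(vec, 2, sqrt(pmax(e$values[seq_len(k)], 0)), "*")
  rownames(scores) <- rownames(G)
  colnames(scores) <- paste0("PC", seq_len(k))
  list(eigenvalues = e$values, scores = scores,
       explained = e$values[seq_len(k)] / pos_total)
}

#' Neighbour-joining tree from a genetic distance matrix
#'
#' Classical Saitou-Nei agglomeration (via \code{ape::nj}); on additive
#' distances the tree's path lengths reproduce the input exactly.
#'
#' @param D symmetric distance matrix with zero diagonal.
#' @return an \code{ape} `phylo` tree (unrooted).
#' @export
njTree <- function(D) {
  D <- as.matrix(D)
  if (any(D < 0)) stop("negative distances are not allowed")
  stopifnot(isSymmetric(unname(D), tol = 1e-8),
            all(abs(diag(D)) < 1e-12))
  ape::nj(stats::as.dist(D))
}

#' Partition individuals into families by thresholded relatedness
#'
#' Builds a graph with an edge wherever the pairwise relationship
#' \eqn{G_{ij}} is at or above `threshold` (default 0.1) and takes connected
#' components as families (`method = "components"`); alternatively,
#' complete-linkage clustering cut so every within-family pair satisfies the
#' threshold (`method = "complete"`). Families are numbered by the first
#' appearance of any member along the supplied tree's tip ordering, or input
#' order when no tree is given. Singleton families are allowed.
#'
#' @param G symmetric relationship matrix with sample dimnames.
#' @param threshold minimum relationship defining a family link.
#' @param tree optional `phylo` object used only for family numbering.
#' @param method `"components"` (default) or `"complete"`.
#' @return list with `family` (named integer vector), `sizes` (table) and
#'   `n_families`.
#' @export
partitionFamilies <- function(G, threshold = 0.1, tree = NULL,
                              method = c("components", "complete")) {
  method <- match.arg(method)
  n <- nrow(G)
  ids <- rownames(G)
  if (is.null(ids)) ids <- paste0("S", seq_len(n))
  if (method == "components") {
    adj <- (G >= threshold)
    diag(adj) <- FALSE
    gr <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    comp <- igraph::components(gr)$membership
  } else {
    d <- -G
    diag(d) <- 0
    comp <- stats::cutree(stats::hclust(stats::as.dist(d),
                                        method = "complete"),
                          h = -threshold)
  }
  ord <- seq_len(n)
  if (!is.null(tree)) {
    tips <- tree$tip.label[tree$edge[tree$edge[, 2] <= length(tree$tip.label), 2]]
    ord <- match(tips, ids)
    ord <- c(ord[!is.na(ord)], setdiff(seq_len(n), ord))
  }
  first_seen <- unique(comp[ord])
  fam <- match(comp, first_seen)
  names(fam) <- ids
  list(family = fam, sizes = table(fam), n_families = length(first_seen))
}
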