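# Population-genetic statistics on plastome alignments: haplotype
# collapsing under complete deletion, haplotype diversity (Hd), nucleotide
# diversity (Pi), p- and Tamura-Nei (TN93) distances, a Hudson-style
# distance-based Fst, PCA on indicator-encoded SNVs, and a neighbor-joining
# tree front-end.

# columns kept under complete deletion: every row an unambiguous base
retained_columns <- function(m) {
  which(colSums(m == "A" | m == "C" | m == "G" | m == "T") == nrow(m))
}

#' Collapse samples into haplotypes (complete deletion)
#'
#' Removes every alignment column holding a gap or an ambiguous state in any
#' sample, then merges identical remaining sequences.  Haplotype ids are
#' assigned in first-occurrence order (`h1`, `h2`, ...).
#'
#' @param aln a [plast_alignment()] (or character matrix).
#' @return object of class `haplotype_set`: data.frame `haplotypes`
#'   (haplotype_id, n_members, members as list-column, sequence), and
#'   `retained_columns` (alignment column indices kept).
#' @export
collapse_haplotypes <- function(aln) {
  m <- if (inherits(aln, "plast_alignment")) unclass(aln) else aln
  stopifnot(is.matrix(m), nrow(m) >= 2L)
  keep <- retained_columns(m)
  if (length(keep) == 0L) {
    stop("no informative sites: all columns removed by complete deletion",
         call. = FALSE)
  }
  sub <- m[, keep, drop = FALSE]
  seqs <- apply(sub, 1L, paste, collapse = "")
  first <- !duplicated(seqs)
  reps <- seqs[first]
  hid <- paste0("h", seq_along(reps))
  assign <- hid[match(seqs, reps)]
  members <- split(rownames(m), factor(assign, levels = hid))
  hap <- data.frame(haplotype_id = hid,
                    n_members = lengths(members),
                    sequence = reps,
                    stringsAsFactors = FALSE, row.names = NULL)
  hap$members <- unname(members)
  structure(list(haplotypes = hap, retained_columns = keep,
                 sample_assignment = stats::setNames(assign, rownames(m))),
            class = "haplotype_set")
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat(sprintf("<haplotype_set> %d haplotype(s), %d sample(s), %d retained column(s)\n",
              nrow(x$haplotypes), sum(x$haplotypes$n_members),
              length(x$retained_columns)))
  invisible(x)
}

#' Haplotype diversity
#'
#' `Hd = n (1 - sum p_i^2) / (n - 1)`: the bias-corrected probability that
#' two samples drawn without replacement carry different haplotypes.
#'
#' @param x a [collapse_haplotypes()] result, or an integer vector of
#'   haplotype member counts.
#' @return Hd in `[0, 1]`.
#' @export
haplotype_diversity <- function(x) {
  counts <- if (inherits(x, "haplotype_set")) x$haplotypes$n_members
            else as.integer(x)
  n <- sum(counts)
  if (n < 2L) stop("haplotype diversity needs n >= 2 samples", call. = FALSE)
  p <- counts / n
  n * (1 - sum(p^2)) / (n - 1)
}

#' Nucleotide diversity (Pi)
#'
#' Mean over unordered sample pairs of the per-site difference proportion at
#' the columns retained after complete deletion over the analyzed members.
#'
#' @param aln a [plast_alignment()] or character matrix.
#' @param members optional subset of sample ids (default: all rows).
#' @param snv_only restrict to the alignment's substitution columns before
#'   deletion (divisor is then the retained SNV-column count).
#' @return Pi (differences per retained site, >= 0).
#' @export
nucleotide_diversity <- function(aln, members = NULL, snv_only = FALSE) {
  m <- if (inherits(aln, "plast_alignment")) unclass(aln) else aln
  if (snv_only) {
    stopifnot(inherits(aln, "plast_alignment"))
    m <- snv_matrix(aln)
  }
  if (!is.null(members)) {
    stopifnot(all(members %in% rownames(m)))
    m <- m[members, , drop = FALSE]
  }
  if (nrow(m) < 2L) stop("nucleotide diversity needs >= 2 members",
                         call. = FALSE)
  keep <- retained_columns(m)
  if (length(keep) == 0L) stop("no retained columns", call. = FALSE)
  sub <- m[, keep, drop = FALSE]
  n <- nrow(sub)
  tot <- 0
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      tot <- tot + sum(sub[i, ] != sub[j, ])
    }
  }
  npairs <- n * (n - 1) / 2
  (tot / length(keep)) / npairs
}

# sites where both sequences carry an unambiguous base (pairwise deletion)
pair_valid_sites <- function(a, b) {
  ok <- (a %in% c("A", "C", "G", "T")) & (b %in% c("A", "C", "G", "T"))
  list(a = a[ok], b = b[ok])
}

#' Proportion-of-differences (p-) distance
#'
#' @param a,b equal-length character vectors or strings; gapped/ambiguous
#'   sites are dropped pairwise.
#' @return p-distance in `[0, 1]`.
#' @export
p_distance <- function(a, b) {
  if (is.character(a) && length(a) == 1L) a <- seq_chars(a)
  if (is.character(b) && length(b) == 1L) b <- seq_chars(b)
  stopifnot(length(a) == length(b))
  v <- pair_valid_sites(a, b)
  if (length(v$a) == 0L) stop("no comparable sites", call. = FALSE)
  mean(v$a != v$b)
}

#' Tamura-Nei (TN93) distance
#'
#' Maximum-likelihood distance under the TN93 model, separating purine
#' transitions (P1: A<->G), pyrimidine transitions (P2: C<->T) and
#' transversions (Q), with base frequencies estimated from the pooled pair:
#' \deqn{d = -k1 ln(1 - P1/(2 k1) \pi_R ... )} (the standard closed form;
#' see the methods vignette for the full expression and symbols).
#'
#' @param a,b equal-length sequences (strings or character vectors);
#'   gapped/ambiguous sites dropped pairwise.
#' @return distance in substitutions/site.  Errors with condition class
#'   `tn93_saturation` when a logarithm argument is nonpositive; falls back
#'   to [p_distance()] with a warning when a purine or pyrimidine frequency
#'   class is empty.
#' @export
tn93_distance <- function(a, b) {
  if (is.character(a) && length(a) == 1L) a <- seq_chars(a)
  if (is.character(b) && length(b) == 1L) b <- seq_chars(b)
  stopifnot(length(a) == length(b))
  v <- pair_valid_sites(a, b)
  n <- length(v$a)
  if (n == 0L) stop("no comparable sites", call. = FALSE)
  pool <- c(v$a, v$b)
  pa <- mean(pool == "A"); pc <- mean(pool == "C")
  pg <- mean(pool == "G"); pt <- mean(pool == "T")
  pr <- pa + pg; py <- pc + pt
  diff <- v$a != v$b
  pairs <- paste0(pmin(v$a, v$b), pmax(v$a, v$b))
  P1 <- mean(diff & pairs == "AG")
  P2 <- mean(diff & pairs == "CT")
  Q <- mean(diff) - P1 - P2
  # 0/0 guards: a term with no observed substitutions of its kind
  # contributes zero even when its frequency product vanishes
  ratio <- function(num, den) {
    if (num == 0) 0 else if (den == 0) Inf else num / den
  }
  arg1 <- 1 - ratio(pr * P1, 2 * pa * pg) - ratio(Q, 2 * pr)
  arg2 <- 1 - ratio(py * P2, 2 * pt * pc) - ratio(Q, 2 * py)
  arg3 <- 1 - ratio(Q, 2 * pr * py)
  if (!is.finite(arg1) || !is.finite(arg2) || !is.finite(arg3) ||
      arg1 <= 0 || arg2 <= 0 || arg3 <= 0) {
    stop(structure(class = c("tn93_saturation", "error", "condition"),
                   list(message = "distance undefined (saturation)",
                        call = NULL)))
  }
  if (pr == 0 || py == 0) {
    warning("degenerate base composition (single purine/pyrimidine ",
            "class); falling back to p-distance", call. = FALSE)
    return(mean(diff))
  }
  c1 <- 2 * pa * pg / pr
  c2 <- 2 * pt * pc / py
  t1 <- if (c1 > 0) -c1 * log(arg1) else 0
  t2 <- if (c2 > 0) -c2 * log(arg2) else 0
  t3 <- -2 * (pr * py - pa * pg * py / pr - pt * pc * pr / py) * log(arg3)
  t1 + t2 + t3
}

#' Pairwise distance matrix
#'
#' @param seqs named character vector of equal-length sequences, or a
#'   character matrix with rownames.
#' @param model `"tn93"` or `"p"`.
#' @param saturation_fallback under `"tn93"`, replace saturated pairs by
#'   their p-distance (with one warning) instead of erroring.
#' @return object of class `plast_dist`: `labels`, symmetric `matrix`
#'   (zero diagonal), `model`.
#' @export
dist_matrix <- function(seqs, model = c("tn93", "p"),
                        saturation_fallback = FALSE) {
  model <- match.arg(model)
  m <- if (is.matrix(seqs)) seqs else
    do.call(rbind, lapply(seqs, seq_chars))
  labels <- rownames(m)
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  fell_back <- FALSE
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      val <- if (model == "p") p_distance(m[i, ], m[j, ]) else {
        tryCatch(tn93_distance(m[i, ], m[j, ]),
                 tn93_saturation = function(e) {
                   if (!saturation_fallback) stop(e)
                   fell_back <<- TRUE
                   p_distance(m[i, ], m[j, ])
                 })
      }
      d[i, j] <- d[j, i] <- val
    }
  }
  if (fell_back) {
    warning("TN93 saturated for some pairs; p-distance used there",
            call. = FALSE)
  }
  structure(list(labels = labels, matrix = d, model = model),
            class = "plast_dist")
}

#' Pairwise Fst between two clusters
#'
#' Hudson-style distance-based estimator on the alignment's SNV columns:
#' `Fst = 1 - Hw / Hb` with `Hw` the mean within-cluster pairwise distance
#' (averaged over the two clusters) and `Hb` the mean between-cluster
#' pairwise distance.  Small negative estimates are floored at 0 and
#' flagged.  Under the TN93 model, saturated pairs fall back to p-distance
#' (flagged by a warning), so that boundary cases stay defined.
#'
#' @param aln a [plast_alignment()].
#' @param clusterA,clusterB sample-id vectors (>= 2 each, disjoint).
#' @param model `"tn93"` or `"p"`.
#' @return Fst (<= 1), `NA` when the between-cluster mean distance is zero;
#'   attribute `floored` marks a negative estimate clipped to 0.
#' @export
pairwise_fst <- function(aln, clusterA, clusterB, model = c("tn93", "p")) {
  model <- match.arg(model)
  stopifnot(length(clusterA) >= 2L, length(clusterB) >= 2L,
            length(intersect(clusterA, clusterB)) == 0L)
  snv <- snv_matrix(aln)
  all_ids <- c(clusterA, clusterB)
  stopifnot(all(all_ids %in% rownames(snv)))
  sub <- snv[all_ids, , drop = FALSE]
  if (ncol(sub) == 0L) return(NA_real_)
  dm <- suppressWarnings(
    dist_matrix(sub, model = model, saturation_fallback = TRUE))$matrix
  within_mean <- function(ids) {
    dd <- dm[ids, ids, drop = FALSE]
    mean(dd[upper.tri(dd)])
  }
  hw <- (within_mean(clusterA) + within_mean(clusterB)) / 2
  hb <- mean(dm[clusterA, clusterB])
  if (hb == 0) return(NA_real_)
  fst <- 1 - hw / hb
  floored <- FALSE
  if (fst < 0) { fst <- 0; floored <- TRUE }
  attr(fst, "floored") <- floored
  fst
}

#' Fst matrix over all cluster pairs
#'
#' @param aln a [plast_alignment()].
#' @param clusters data.frame with columns `sample_id`, `cluster`.
#' @param model distance model.
#' @return symmetric matrix of pairwise Fst (diagonal 0); cluster pairs with
#'   fewer than 2 members each are `NA`.
#' @export
fst_matrix <- function(aln, clusters, model = c("tn93", "p")) {
  model <- match.arg(model)
  labs <- unique(clusters$cluster)
  k <- length(labs)
  out <- matrix(NA_real_, k, k, dimnames = list(labs, labs))
  diag(out) <- 0
  memb <- split(clusters$sample_id, clusters$cluster)
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      a <- memb[[labs[i]]]; b <- memb[[labs[j]]]
      if (length(a) >= 2L && length(b) >= 2L) {
        v <- pairwise_fst(aln, a, b, model = model)
        out[i, j] <- out[j, i] <- as.numeric(v)
      }
    }
  }
  out
}

#' PCA coordinates from an SNV matrix
#'
#' Each SNV column is indicator-encoded (major allele 0; one 0/1 indicator
#' per minor allele; ties for the major allele resolved alphabetically),
#' the indicator matrix is column-centered, and coordinates come from the
#' leading principal components.  Component signs are fixed by making each
#' component's largest-magnitude loading positive.
#'
#' @param snv character matrix from [snv_matrix()] (>= 3 samples).
#' @param k number of components (default `min(n - 1, 10)`).
#' @return list: `coords` (samples x components), `explained`
#'   (variance fractions), `loadings`.
#' @export
pca_coordinates <- function(snv, k = NULL) {
  stopifnot(is.matrix(snv), nrow(snv) >= 3L, ncol(snv) >= 1L)
  blocks <- list()
  for (j in seq_len(ncol(snv))) {
    col <- snv[, j]
    tab <- sort(table(col), decreasing = TRUE)
    states <- names(tab)
    major <- sort(states[tab == max(tab)])[1]
    minors <- setdiff(states, major)
    for (s in minors) {
      blocks[[length(blocks) + 1L]] <- as.numeric(col == s)
    }
  }
  if (length(blocks) == 0L) {
    stop("zero-variance SNV matrix", call. = FALSE)
  }
  x <- do.call(cbind, blocks)
  rownames(x) <- rownames(snv)
  x <- scale(x, center = TRUE, scale = FALSE)
  if (all(abs(x) < .Machine$double.eps)) {
    stop("zero-variance SNV matrix", call. = FALSE)
  }
  if (is.null(k)) k <- min(nrow(x) - 1L, 10L)
  pc <- stats::prcomp(x, center = FALSE)
  k <- min(k, ncol(pc$rotation))
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  coords <- pc$x[, seq_len(k), drop = FALSE]
  for (c_i in seq_len(k)) {
    imax <- which.max(abs(rot[, c_i]))
    if (rot[imax, c_i] < 0) {
      rot[, c_i] <- -rot[, c_i]
      coords[, c_i] <- -coords[, c_i]
    }
  }
  explained <- pc$sdev^2 / sum(pc$sdev^2)
  list(coords = coords, explained = explained[seq_len(k)], loadings = rot)
}

#' Neighbor-joining tree
#'
#' Standard NJ agglomeration (via \pkg{ape}) with negative branch lengths
#' floored at 0 and the deficit transferred to the sister edge, keeping
#' leaf-to-leaf path lengths unchanged where possible.
#'
#' @param dm a [dist_matrix()] result, `dist`, or symmetric matrix.
#' @return `phylo` tree (unrooted).
#' @export
nj_tree <- function(dm) {
  m <- if (inherits(dm, "plast_dist")) dm$matrix
       else if (inherits(dm, "dist")) as.matrix(dm)
       else dm
  stopifnot(is.matrix(m), nrow(m) >= 3L)
  if (!isSymmetric(unname(m), tol = 1e-10)) {
    stop("distance matrix must be symmetric", call. = FALSE)
  }
  tr <- ape::nj(stats::as.dist(m))
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    parent <- tr$edge[e, 1]
    sibs <- setdiff(which(tr$edge[, 1] == parent), e)
    if (length(sibs) > 0) {
      tr$edge.length[sibs[1]] <- tr$edge.length[sibs[1]] + tr$edge.length[e]
    }
    tr$edge.length[e] <- 0
  }
  tr
}

#' Per-cluster diversity table
#'
#' @param aln a [plast_alignment()].
#' @param clusters data.frame `sample_id`, `cluster`.
#' @param snv_only compute Pi on SNV columns only.
#' @return data.frame: cluster, n, h (haplotype count), Hd, Pi.
#' @export
diversity_by_cluster <- function(aln, clusters, snv_only = FALSE) {
  m <- unclass(aln)
  rows <- lapply(split(clusters$sample_id, clusters$cluster), identity)
  out <- lapply(names(rows), function(cl) {
    ids <- rows[[cl]]
    n <- length(ids)
    if (n < 2L) {
      return(data.frame(cluster = cl, n = n, h = NA_integer_,
                        Hd = NA_real_, Pi = NA_real_))
    }
    hs <- collapse_haplotypes(m[ids, , drop = FALSE])
    data.frame(cluster = cl, n = n, h = nrow(hs$haplotypes),
               Hd = haplotype_diversity(hs),
               Pi = nucleotide_diversity(aln, members = ids,
                                         snv_only = snv_only))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
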