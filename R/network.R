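# Haplotype networks: minimum spanning network (union of all MSTs of the
# Hamming-distance graph) and a Bandelt-style median-joining network that
# augments the node set with majority-consensus median (Steiner) vectors
# whenever they reduce the minimum-spanning cost.

hamming_matrix <- function(seqmat) {
  n <- nrow(seqmat)
  d <- matrix(0L, n, n)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        d[i, j] <- d[j, i] <- sum(seqmat[i, ] != seqmat[j, ])
      }
    }
  }
  d
}

# union-find helpers (vector of parents, path halving)
uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

# Edges of the (epsilon-relaxed) minimum spanning network.  An edge (i, j)
# of weight w is kept when w <= w_connect(i, j) + epsilon, where w_connect
# is the weight class at which the Kruskal sweep first joins the
# components of i and j.  epsilon = 0 gives the exact union of all MSTs.
msn_edge_list <- function(d, epsilon = 0L) {
  n <- nrow(d)
  if (n < 2L) {
    return(data.frame(from = integer(0), to = integer(0),
                      weight = integer(0)))
  }
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  w <- d[pairs]
  ord <- order(w, pairs[, 1], pairs[, 2])
  pairs <- pairs[ord, , drop = FALSE]
  w <- w[ord]
  parent <- seq_len(n)
  # first pass: Kruskal connection threshold per component pair is implied
  # by sweeping weight classes; collect kept edges on the fly
  keep <- logical(length(w))
  wconnect <- rep(NA_real_, length(w))
  for (wc in unique(w)) {
    in_class <- which(w == wc)
    # components as of weights < wc
    comp <- vapply(seq_len(n), function(i) uf_find(parent, i), integer(1))
    wconnect[in_class] <- ifelse(
      comp[pairs[in_class, 1]] != comp[pairs[in_class, 2]], wc, NA_real_)
    keep[in_class] <- comp[pairs[in_class, 1]] != comp[pairs[in_class, 2]]
    for (e in in_class) {
      ra <- uf_find(parent, pairs[e, 1]); rb <- uf_find(parent, pairs[e, 2])
      if (ra != rb) parent[ra] <- rb
    }
  }
  if (epsilon > 0L) {
    # connection weight between the components of i and j (from the strict
    # sweep): recompute per edge as the smallest kept-edge path max; the
    # relaxation keeps an edge whose weight is within epsilon of the class
    # at which its endpoints' components first met
    conn <- connection_weights(d)
    keep <- w <= conn[cbind(pairs[, 1], pairs[, 2])] + epsilon
  }
  data.frame(from = pairs[keep, 1], to = pairs[keep, 2], weight = w[keep])
}

# minimax path weight (bottleneck distance) between all node pairs; the
# weight class at which two nodes join during the Kruskal sweep
connection_weights <- function(d) {
  n <- nrow(d)
  conn <- matrix(Inf, n, n); diag(conn) <- 0
  parent <- seq_len(n)
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  w <- d[pairs]
  ord <- order(w)
  for (wc in unique(sort(w))) {
    for (e in ord[w[ord] == wc]) {
      ra <- uf_find(parent, pairs[e, 1]); rb <- uf_find(parent, pairs[e, 2])
      if (ra != rb) parent[ra] <- rb
    }
    comp <- vapply(seq_len(n), function(i) uf_find(parent, i), integer(1))
    joined <- outer(comp, comp, "==") & !is.finite(conn)
    conn[joined] <- wc
  }
  conn
}

# MST total cost of a set of sequences (rows of a character matrix)
mst_cost <- function(seqmat) {
  mst_cost_d(hamming_matrix(seqmat))
}

# MST total cost from a precomputed distance matrix (Kruskal)
mst_cost_d <- function(d) {
  n <- nrow(d)
  if (n < 2L) return(0L)
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  w <- d[pairs]
  ord <- order(w)
  parent <- seq_len(n)
  cost <- 0L; used <- 0L
  for (e in ord) {
    ra <- uf_find(parent, pairs[e, 1]); rb <- uf_find(parent, pairs[e, 2])
    if (ra != rb) {
      parent[ra] <- rb
      cost <- cost + w[e]
      used <- used + 1L
      if (used == n - 1L) break
    }
  }
  cost
}

haplo_network_obj <- function(nodes, edges) {
  structure(list(nodes = nodes, edges = edges), class = "haplo_network")
}

#' @export
print.haplo_network <- function(x, ...) {
  cat(sprintf("<haplo_network> %d node(s) (%d median), %d edge(s), cost %d\n",
              nrow(x$nodes), sum(x$nodes$is_median), nrow(x$edges),
              sum(x$edges$weight[x$edges$in_mst])))
  invisible(x)
}

# assemble the network object from a node sequence matrix + metadata
build_network <- function(seqmat, ids, is_median, members, epsilon = 0L) {
  d <- hamming_matrix(seqmat)
  el <- msn_edge_list(d, epsilon = epsilon)
  # mark one deterministic MST inside the MSN for cost reporting
  in_mst <- rep(FALSE, nrow(el))
  if (nrow(el) > 0L) {
    parent <- seq_len(nrow(seqmat))
    ord <- order(el$weight, el$from, el$to)
    for (e in ord) {
      ra <- uf_find(parent, el$from[e]); rb <- uf_find(parent, el$to[e])
      if (ra != rb) { parent[ra] <- rb; in_mst[e] <- TRUE }
    }
  }
  nodes <- data.frame(id = ids, is_median = is_median,
                      n_members = lengths(members),
                      sequence = apply(seqmat, 1L, paste, collapse = ""),
                      stringsAsFactors = FALSE)
  nodes$members <- members
  edges <- data.frame(from = ids[el$from], to = ids[el$to],
                      weight = el$weight, in_mst = in_mst,
                      stringsAsFactors = FALSE)
  haplo_network_obj(nodes, edges)
}

hs_seqmat <- function(hs) {
  m <- do.call(rbind, lapply(hs$haplotypes$sequence, seq_chars))
  rownames(m) <- hs$haplotypes$haplotype_id
  m
}

#' Minimum spanning network of a haplotype set
#'
#' Union of all minimum spanning trees of the complete Hamming-distance
#' graph over the observed haplotypes.
#'
#' @param hs a [collapse_haplotypes()] result.
#' @return a `haplo_network` (nodes, edges; `in_mst` marks one
#'   deterministic MST inside the network).
#' @export
minimum_spanning_network <- function(hs) {
  stopifnot(inherits(hs, "haplotype_set"))
  seqmat <- hs_seqmat(hs)
  build_network(seqmat, hs$haplotypes$haplotype_id,
                rep(FALSE, nrow(seqmat)), hs$haplotypes$members)
}

# majority median of three aligned sequences; a three-way tie takes the
# state of the first row (callers order rows by node rank)
triplet_median <- function(three) {
  a <- three[1L, ]; b <- three[2L, ]; c <- three[3L, ]
  med <- a                       # a wins all ties and all a-majorities
  bc <- a != b & b == c          # only a strict b==c majority overrides
  med[bc] <- b[bc]
  med
}

#' Median-joining haplotype network
#'
#' Iterates: build the (epsilon-relaxed) minimum spanning network over the
#' current node set; for every triplet of mutually connected nodes compute
#' the per-column majority median; add the median that most reduces the
#' minimum-spanning cost; repeat to fixpoint.  Finally, unsampled median
#' vectors of degree < 3 are removed and the network re-linked.
#'
#' @param hs a [collapse_haplotypes()] result.
#' @param epsilon nonnegative integer relaxation of the MSN connection
#'   threshold (default 0).
#' @param max_medians safety cap on added median vectors.
#' @return a `haplo_network`; median nodes have ids `mv1`, `mv2`, ... and
#'   zero members.
#' @export
median_joining_network <- function(hs, epsilon = 0L, max_medians = NULL) {
  stopifnot(inherits(hs, "haplotype_set"), epsilon >= 0L)
  obs <- hs_seqmat(hs)
  n_obs <- nrow(obs)
  if (is.null(max_medians)) max_medians <- 2L * n_obs + 8L
  seqmat <- obs
  ids <- hs$haplotypes$haplotype_id
  is_median <- rep(FALSE, n_obs)
  n_mv <- 0L
  repeat {
    if (n_mv >= max_medians) break
    d <- hamming_matrix(seqmat)
    el <- msn_edge_list(d, epsilon = epsilon)
    cur_cost <- mst_cost(seqmat)
    adj <- matrix(FALSE, nrow(seqmat), nrow(seqmat))
    adj[cbind(el$from, el$to)] <- TRUE
    adj <- adj | t(adj)
    # connected triplets, nodes ordered by creation rank (ties in the
    # majority vote take the state of the lowest-rank node)
    cand_seqs <- character(0)
    nn <- nrow(seqmat)
    for (i in seq_len(nn)) {
      nb <- which(adj[i, ] & seq_len(nn) > i)
      if (length(nb) < 2L) next
      for (a in seq_along(nb[-length(nb)])) {
        for (b in (a + 1L):length(nb)) {
          j <- nb[a]; k <- nb[b]
          if (!adj[j, k]) next
          med <- triplet_median(seqmat[c(i, j, k), , drop = FALSE])
          cand_seqs <- c(cand_seqs, paste(med, collapse = ""))
        }
      }
    }
    cand_seqs <- setdiff(unique(cand_seqs),
                         apply(seqmat, 1L, paste, collapse = ""))
    if (length(cand_seqs) == 0L) break
    gains <- vapply(cand_seqs, function(s) {
      cand <- seq_chars(s)
      newrow <- vapply(seq_len(nn), function(i)
        sum(seqmat[i, ] != cand), integer(1))
      d_aug <- rbind(cbind(d, newrow), c(newrow, 0L))
      cur_cost - mst_cost_d(d_aug)
    }, numeric(1))
    best_gain <- max(gains)
    if (best_gain <= 0) break
    best <- sort(cand_seqs[gains == best_gain])[1]
    n_mv <- n_mv + 1L
    seqmat <- rbind(seqmat, seq_chars(best))
    ids <- c(ids, paste0("mv", n_mv))
    is_median <- c(is_median, TRUE)
  }
  # prune unsampled medians of degree < 3, re-linking after each removal
  repeat {
    d <- hamming_matrix(seqmat)
    el <- msn_edge_list(d, epsilon = epsilon)
    deg <- tabulate(c(el$from, el$to), nbins = nrow(seqmat))
    drop <- which(is_median & deg < 3L)
    if (length(drop) == 0L) break
    keep <- setdiff(seq_len(nrow(seqmat)), drop[1])
    seqmat <- seqmat[keep, , drop = FALSE]
    ids <- ids[keep]
    is_median <- is_median[keep]
  }
  members <- vector("list", length(ids))
  obs_idx <- match(hs$haplotypes$haplotype_id, ids)
  for (i in seq_along(obs_idx)) {
    if (!is.na(obs_idx[i])) {
      members[[obs_idx[i]]] <- hs$haplotypes$members[[i]]
    }
  }
  empty <- vapply(members, is.null, logical(1))
  members[empty] <- list(character(0))
  build_network(seqmat, ids, is_median, members, epsilon = epsilon)
}

#' Attach group composition to network nodes
#'
#' @param net a `haplo_network`.
#' @param groups data.frame with columns `sample_id`, `group`.
#' @return the network with a `composition` list-column on `nodes`
#'   (named count vector per node; empty for median vectors).
#' @export
annotate_composition <- function(net, groups) {
  stopifnot(inherits(net, "haplo_network"))
  lookup <- stats::setNames(as.character(groups$group), groups$sample_id)
  comp <- lapply(seq_len(nrow(net$nodes)), function(i) {
    mem <- net$nodes$members[[i]]
    if (length(mem) == 0L) return(integer(0))
    unknown <- setdiff(mem, names(lookup))
    if (length(unknown) > 0L) {
      stop("samples missing from group table: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    tab <- table(lookup[mem])
    stats::setNames(as.integer(tab), names(tab))
  })
  net$nodes$composition <- comp
  net
}

#' Network node and edge tables for export
#'
#' @param net a `haplo_network`.
#' @return list of two data.frames: `nodes` (id, is_median, n_members,
#'   composition as JSON) and `edges` (node1, node2, weight).
#' @export
network_tables <- function(net) {
  comp_json <- if ("composition" %in% names(net$nodes)) {
    vapply(net$nodes$composition, function(x)
      as.character(jsonlite::toJSON(as.list(x), auto_unbox = TRUE)),
      character(1))
  } else rep("{}", nrow(net$nodes))
  nodes <- data.frame(id = net$nodes$id, is_median = net$nodes$is_median,
                      n_members = net$nodes$n_members,
                      composition = comp_json, stringsAsFactors = FALSE)
  edges <- data.frame(node1 = net$edges$from, node2 = net$edges$to,
                      weight = net$edges$weight, stringsAsFactors = FALSE)
  list(nodes = nodes, edges = edges)
}
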