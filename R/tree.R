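# integer encoding: A=1 G=2 C=3 T=4, anything else (N, gap) = 5 -> excluded
encode_sites <- function(seq) {
  ch <- strsplit(toupper(seq), "")[[1]]
  m <- match(ch, c("A", "G", "C", "T"))
  m[is.na(m)] <- 5L
  m
}

pair_site_counts <- function(mi, mj) {
  valid <- mi < 5L & mj < 5L
  nv <- sum(valid)
  diff <- valid & (mi != mj)
  # transition: both purines (A/G) or both pyrimidines (C/T) but different
  transitions <- sum(diff & ((mi <= 2L) == (mj <= 2L)))
  transversions <- sum(diff) - transitions
  list(n = nv, ts = transitions, tv = transversions)
}

k2p_from_PQ <- function(P, Q, label = NULL) {
  a1 <- 1 - 2 * P - Q
  a2 <- 1 - 2 * Q
  if (a1 <= 0 || a2 <= 0)
    stop("K2P distance undefined (substitution saturation)",
         if (!is.null(label)) paste0(" for pair ", label) else "")
  -0.5 * log(a1 * sqrt(a2))
}

#' Kimura 2-parameter distance between two aligned sequences
#'
#' `d = -1/2 * ln((1 - 2P - Q) * sqrt(1 - 2Q))` with `P` the transition and
#' `Q` the transversion fraction. Sites with `N` or a gap in either sequence
#' are excluded pairwise. Sequences must be equal length (a fixed barcode
#' region); saturation (log argument <= 0) errors, naming the pair.
#'
#' @param seq_a,seq_b character scalars.
#' @return non-negative numeric distance.
#' @export
k2p_distance <- function(seq_a, seq_b) {
  mi <- encode_sites(seq_a); mj <- encode_sites(seq_b)
  if (length(mi) != length(mj))
    stop("sequences must be of equal length (aligned barcode region)")
  cnt <- pair_site_counts(mi, mj)
  if (cnt$n == 0) stop("no comparable sites between the sequences")
  k2p_from_PQ(cnt$ts / cnt$n, cnt$tv / cnt$n)
}

#' Proportion of differing sites (p-distance)
#'
#' @inheritParams k2p_distance
#' @return fraction in `[0, 1]`; sites with `N`/gap excluded pairwise.
#' @export
p_distance <- function(seq_a, seq_b) {
  mi <- encode_sites(seq_a); mj <- encode_sites(seq_b)
  if (length(mi) != length(mj))
    stop("sequences must be of equal length (aligned barcode region)")
  valid <- mi < 5L & mj < 5L
  if (sum(valid) == 0) stop("no comparable sites between the sequences")
  sum(valid & mi != mj) / sum(valid)
}

#' Pairwise distance matrix for a set of aligned sequences
#'
#' @param seqs named character vector of equal-length sequences.
#' @param model "k2p" (barcoding convention, default) or "p".
#' @return symmetric numeric matrix with zero diagonal.
#' @export
distance_matrix <- function(seqs, model = c("k2p", "p")) {
  model <- match.arg(model)
  n <- length(seqs)
  stopifnot(n >= 2, !is.null(names(seqs)))
  enc <- lapply(seqs, encode_sites)
  D <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    d <- if (model == "k2p") {
      cnt <- pair_site_counts(enc[[i]], enc[[j]])
      if (cnt$n == 0) stop("no comparable sites for pair ",
                           names(seqs)[i], "/", names(seqs)[j])
      k2p_from_PQ(cnt$ts / cnt$n, cnt$tv / cnt$n,
                  paste0(names(seqs)[i], "/", names(seqs)[j]))
    } else p_distance(seqs[[i]], seqs[[j]])
    D[i, j] <- D[j, i] <- d
  }
  D
}

#' Neighbour-joining tree (Saitou-Nei)
#'
#' Agglomerative NJ: iteratively joins the pair minimising the Q-criterion
#' `Q_ij = (n-2) d_ij - r_i - r_j`. Ties are broken by lexicographic label
#' order (a merged cluster inherits its lexicographically smaller label), so
#' the result is deterministic and invariant to input order. Negative branch
#' lengths are clamped to zero. For an additive distance matrix, path lengths
#' on the returned tree reproduce the input distances exactly.
#'
#' @param D symmetric distance matrix with taxon dimnames (or a `dist`).
#' @return unrooted `phylo` (ape) tree.
#' @export
neighbor_joining <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n < 3) stop("neighbour-joining requires at least 3 taxa")
  if (is.null(rownames(D))) stop("distance matrix must have taxon labels")
  if (any(abs(D - t(D)) > 1e-12)) stop("distance matrix must be symmetric")
  if (any(D < 0)) stop("distances must be non-negative")
  labs <- rownames(D)
  nwk <- labs          # newick fragment per active cluster
  key <- labs          # tie-break label per active cluster
  fmt <- function(x) sprintf("%.17g", max(x, 0) + 0)  # +0 normalises -0

  while (n > 3) {
    r <- rowSums(D)
    Q <- (n - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    mq <- min(Q)
    cand <- which(Q <= mq + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    pk <- apply(cand, 1, function(ij) {
      k <- sort(c(key[ij[1]], key[ij[2]]))
      paste(k[1], k[2], sep = "\r")
    })
    sel <- cand[order(pk)[1], ]
    i <- sel[[1]]; j <- sel[[2]]
    vi <- 0.5 * D[i, j] + (r[i] - r[j]) / (2 * (n - 2))
    vj <- D[i, j] - vi
    new_nwk <- sprintf("(%s:%s,%s:%s)", nwk[i], fmt(vi), nwk[j], fmt(vj))
    new_key <- min(key[i], key[j])
    dk <- 0.5 * (D[i, ] + D[j, ] - D[i, j])
    keep <- setdiff(seq_len(n), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dk[keep]),
                c(dk[keep], 0))
    nwk <- c(nwk[keep], new_nwk)
    key <- c(key[keep], new_key)
    rownames(D2) <- colnames(D2) <- key
    D <- D2
    n <- n - 1
  }
  va <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  vb <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  vc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  txt <- sprintf("(%s:%s,%s:%s,%s:%s);", nwk[1], fmt(va), nwk[2], fmt(vb),
                 nwk[3], fmt(vc))
  ape::read.tree(text = txt)
}

#' Internal bipartitions of an unrooted tree
#'
#' One canonical key per internal edge: the tip set on the side **not**
#' containing the alphabetically first tip, sorted and joined with `"|"`.
#' Trivial (pendant) splits are excluded.
#'
#' @param tree a `phylo` object.
#' @return named character vector, names = child node number of the edge.
#' @export
tree_bipartitions <- function(tree) {
  nt <- length(tree$tip.label)
  anchor <- sort(tree$tip.label)[1]
  po <- ape::reorder.phylo(tree, "postorder")
  desc <- vector("list", nt + tree$Nnode)
  for (i in seq_len(nt)) desc[[i]] <- tree$tip.label[i]
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1]; ch <- po$edge[e, 2]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  keys <- character(0)
  root <- nt + 1L
  for (e in seq_len(nrow(tree$edge))) {
    ch <- tree$edge[e, 2]
    if (ch <= nt || ch == root) next
    side <- desc[[ch]]
    if (length(side) <= 1 || length(side) >= nt - 1) next
    if (anchor %in% side) side <- setdiff(tree$tip.label, side)
    keys[[as.character(ch)]] <- paste(sort(side), collapse = "|")
  }
  keys
}

#' Neighbour-joining tree with bootstrap supports
#'
#' Builds the full-data NJ tree, then resamples alignment columns with
#' replacement `n_reps` times, rebuilds the tree per replicate, and maps onto
#' each internal edge of the full-data tree the percentage of replicates
#' whose tree contains that bipartition (supports-on-full-tree convention,
#' not a consensus tree). Replicates whose distance matrix is undefined
#' (K2P saturation) are skipped and counted in `attr(, "skipped")`. Taxa are
#' ordered alphabetically internally, so results do not depend on input
#' order.
#'
#' @param seqs named character vector of equal-length aligned sequences
#'   (>= 3 taxa, >= 2 columns).
#' @param n_reps bootstrap replicates (0 = tree without supports).
#' @param seed integer seed for the resampling.
#' @param model distance model, see [distance_matrix()].
#' @return `phylo` tree; `node.label` holds integer supports in `[0, 100]`
#'   for internal edges (empty at the root and where undefined), and
#'   `attr(, "support")` the unrounded values.
#' @export
bootstrap_support <- function(seqs, n_reps = 1000, seed = 1,
                              model = c("k2p", "p")) {
  model <- match.arg(model)
  stopifnot(length(seqs) >= 3, !is.null(names(seqs)))
  seqs <- seqs[order(names(seqs))]
  L <- unique(nchar(seqs))
  if (length(L) != 1) stop("sequences must be aligned to equal length")
  if (L < 2) stop("alignment must have at least 2 columns")
  full <- neighbor_joining(distance_matrix(seqs, model))
  if (n_reps == 0) return(full)

  enc <- do.call(rbind, lapply(seqs, encode_sites))  # taxa x sites
  n <- length(seqs)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  np <- nrow(pairs)
  # per-site classes per pair: 0 match, 1 transition, 2 transversion, 3 excluded
  cls <- matrix(0L, np, L)
  for (p in seq_len(np)) {
    mi <- enc[pairs[p, 1], ]; mj <- enc[pairs[p, 2], ]
    v <- mi < 5L & mj < 5L
    d <- v & (mi != mj)
    ts <- d & ((mi <= 2L) == (mj <= 2L))
    cls[p, ] <- ifelse(!v, 3L, ifelse(ts, 1L, ifelse(d, 2L, 0L)))
  }
  I_ts <- (cls == 1L) + 0; I_tv <- (cls == 2L) + 0; I_ok <- (cls < 3L) + 0

  target <- tree_bipartitions(full)
  counts <- setNames(numeric(length(target)), unname(target))
  set.seed(seed)
  used <- 0L; skipped <- 0L
  for (b in seq_len(n_reps)) {
    w <- tabulate(sample.int(L, L, replace = TRUE), L)
    nts <- I_ts %*% w; ntv <- I_tv %*% w; nok <- I_ok %*% w
    if (any(nok == 0)) { skipped <- skipped + 1L; next }
    P <- nts / nok; Q <- ntv / nok
    a1 <- 1 - 2 * P - Q; a2 <- 1 - 2 * Q
    if (model == "k2p") {
      if (any(a1 <= 0 | a2 <= 0)) { skipped <- skipped + 1L; next }
      dv <- -0.5 * log(a1 * sqrt(a2))
    } else dv <- (nts + ntv) / nok
    Db <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
    Db[pairs] <- dv
    Db <- Db + t(Db)
    reps <- tree_bipartitions(neighbor_joining(Db))
    hit <- unname(target) %in% reps
    counts[hit] <- counts[hit] + 1
    used <- used + 1L
  }
  support <- if (used > 0) 100 * counts / used else counts * NA
  # map to node labels of the full tree
  nt <- length(full$tip.label)
  node.label <- rep("", full$Nnode)
  for (k in seq_along(target)) {
    node <- as.integer(names(target)[k])
    node.label[node - nt] <- as.character(round(support[k]))
  }
  full$node.label <- node.label
  attr(full, "support") <- setNames(support, unname(target))
  attr(full, "skipped") <- skipped
  full
}
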