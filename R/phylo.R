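# Neighbor-joining trees over SNP allele-sharing distances for the DUP1 and
# DUP2 regions, and the FM-terminal-branch contrast between them. On the
# frozen (recombination-suppressed) duplication all FM chromosomes are
# near-identical, so FM samples coalesce on short terminal branches; on the
# eroded duplication they carry randomized wild-type content and branch like
# the rest of the population.

#' Allele-sharing distance matrix
#'
#' `d_ij` is the mean over co-called sites of `|dosage_i - dosage_j| / 2`
#' (reference-allele dosage 0/1/2), a distance in `[0, 1]` computable from
#' unphased genotypes. Symmetric with zero diagonal; the triangle inequality
#' is not guaranteed.
#'
#' @param obs an `fm_observed`.
#' @param region optional `fm_interval` restricting sites.
#' @param samples optional sample subset (default all).
#' @return symmetric distance matrix with sample dimnames.
#' @export
distance_matrix <- function(obs, region = NULL, samples = NULL) {
  keep <- if (is.null(region)) seq_len(nrow(obs$gt))
          else which(obs$sites$pos >= region$start &
                     obs$sites$pos <= region$end)
  g <- obs$gt[keep, , drop = FALSE]
  if (!is.null(samples)) g <- g[, .group_cols(obs, samples), drop = FALSE]
  m <- ncol(g)
  if (m < 3) stop("need >= 3 samples")
  d <- matrix(0, m, m, dimnames = list(colnames(g), colnames(g)))
  for (i in seq_len(m - 1)) {
    gi <- g[, i]
    for (j in seq(i + 1, m)) {
      shared <- !is.na(gi) & !is.na(g[, j])
      if (!any(shared))
        stop("no co-called sites for pair ", colnames(g)[i], ", ",
             colnames(g)[j])
      d[i, j] <- d[j, i] <- mean(abs(gi[shared] - g[shared, j]) / 2)
    }
  }
  d
}

#' Neighbor-joining tree
#'
#' Saitou--Nei neighbor joining with the standard Q-criterion. Ties in Q are
#' broken deterministically by the lexicographically smallest (sorted) label
#' pair; negative branch lengths are clamped to zero and the total clamped
#' deficit recorded in the returned tree's `"clamped_deficit"` attribute.
#'
#' @param d symmetric distance matrix with labels (zero diagonal).
#' @return an [ape::read.tree()] `phylo` object (unrooted).
#' @export
neighbor_joining <- function(d) {
  if (!is.matrix(d) || !isSymmetric(unname(d), tol = 1e-8))
    stop("distance matrix must be symmetric")
  labs <- rownames(d) %||% colnames(d)
  if (is.null(labs)) stop("distance matrix needs labels")
  n <- nrow(d)
  if (n < 3) stop("need >= 3 taxa")
  deficit <- 0
  clamp <- function(x) {
    neg <- pmin(x, 0)
    deficit <<- deficit - sum(neg)
    pmax(x, 0)
  }
  fmt <- function(x) sprintf("%.12g", x)
  nodes <- labs                  # newick fragment per active node
  active <- seq_len(n)
  D <- d
  while (length(active) > 3) {
    m <- length(active)
    Dm <- D[active, active]
    r <- rowSums(Dm)
    Q <- (m - 2) * Dm - outer(r, r, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    keypair <- apply(cand, 1, function(ij) {
      p <- sort(c(nodes[active[ij[1]]], nodes[active[ij[2]]]))
      paste(p, collapse = "\r")
    })
    pick <- cand[order(keypair)[1], ]
    i <- active[pick[1]]; j <- active[pick[2]]
    dij <- D[i, j]
    bi <- dij / 2 + (r[pick[1]] - r[pick[2]]) / (2 * (m - 2))
    bj <- dij - bi
    bi <- clamp(bi); bj <- clamp(bj)
    new_lab <- paste0("(", nodes[i], ":", fmt(bi), ",",
                      nodes[j], ":", fmt(bj), ")")
    # distances from the new node u to every other active node
    others <- setdiff(active, c(i, j))
    du <- (D[i, others] + D[j, others] - dij) / 2
    D <- rbind(cbind(D, 0), 0)
    u <- nrow(D)
    D[u, others] <- du; D[others, u] <- du
    nodes <- c(nodes, new_lab)
    active <- c(others, u)
  }
  a <- active[1]; b <- active[2]; cn <- active[3]
  ba <- clamp((D[a, b] + D[a, cn] - D[b, cn]) / 2)
  bb <- clamp((D[a, b] + D[b, cn] - D[a, cn]) / 2)
  bc <- clamp((D[a, cn] + D[b, cn] - D[a, b]) / 2)
  nwk <- paste0("(", nodes[a], ":", fmt(ba), ",", nodes[b], ":", fmt(bb),
                ",", nodes[cn], ":", fmt(bc), ");")
  tree <- ape::read.tree(text = nwk)
  attr(tree, "clamped_deficit") <- deficit
  tree
}

#' Mean terminal branch length of a sample set
#'
#' @param tree a `phylo` tree.
#' @param samples tip labels.
#' @return mean length of the pendant edges leading to `samples`.
#' @export
terminal_branch_lengths <- function(tree, samples) {
  tips <- match(samples, tree$tip.label)
  if (anyNA(tips)) stop("samples not in tree: ",
                        paste(samples[is.na(tips)], collapse = ", "))
  el <- tree$edge.length[match(tips, tree$edge[, 2])]
  stats::setNames(el, samples)
}

#' Terminal branch-length contrast between the two duplication trees
#'
#' Compares the mean terminal branch length of FM samples in the DUP1 tree
#' versus the DUP2 tree. Under the confirmed arrangement (frozen DUP1, eroded
#' second DUP2 copy), FM samples sit on much shorter terminal branches in the
#' DUP1 tree, giving a ratio well below 1.
#'
#' @param tree_dup1,tree_dup2 `phylo` trees over the same leaf set.
#' @param fm_samples tip labels of the FM samples.
#' @return list: `mean_dup1`, `mean_dup2`, `ratio` (DUP1/DUP2).
#' @export
branch_length_contrast <- function(tree_dup1, tree_dup2, fm_samples) {
  if (!setequal(tree_dup1$tip.label, tree_dup2$tip.label))
    stop("trees have mismatched leaf sets")
  m1 <- mean(terminal_branch_lengths(tree_dup1, fm_samples))
  m2 <- mean(terminal_branch_lengths(tree_dup2, fm_samples))
  list(mean_dup1 = m1, mean_dup2 = m2,
       ratio = if (m2 > 0) m1 / m2 else NA_real_)
}
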