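#' Tree-guided imputation of missing or ambiguous calls
#'
#' Replaces every `"?"` / `"-"` cell by the state a small-parsimony
#' reconstruction assigns to that tip given the observed cells and a guide
#' tree. The reconstruction is the classic Fitch pass on the binary
#' character: an uppass intersects child state sets (union on conflict) and
#' a downpass hands each node its parent's assignment whenever its own set
#' allows it, so a missing tip inside a derived clade inherits the clade's
#' allele — imputation following the tree topology. The root is constrained
#' to the ancestral (reference) state by default, matching the
#' outgroup-rooted setting; with an unconstrained root the rare residual
#' ambiguity is resolved by a seeded uniform draw, so reruns are
#' reproducible.
#'
#' @param calls Long call tibble (states `0/1/?/-` and curation marks, which
#'   are folded via [normalize_curation_states()] first).
#' @param tree Guide topology: a `genealogy`, `ystar_scenario`, or
#'   [ape::phylo]. Every sample with a missing cell must be a tip.
#' @param seed Integer seed for tie-breaking draws.
#' @param root_state `"0"` to constrain the root to the ancestral allele
#'   (default), or `NULL` for an unconstrained root.
#' @return The call tibble with all cells in `{"0","1"}` and a logical
#'   `imputed` column marking filled cells.
#' @examples
#' phy <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
#' calls <- calls_from_matrix(matrix(
#'   c("1", "?", "0", "0"), 4, 1,
#'   dimnames = list(c("A", "B", "C", "D"), "F00001")
#' ))
#' impute_missing(calls, phy, seed = 1)
#' @export
impute_missing <- function(calls, tree, seed = NULL, root_state = "0") {
  phy <- guide_phylo(tree)
  m <- calls_matrix(normalize_curation_states(calls))
  miss <- m %in% c("?", "-")
  dim(miss) <- dim(m)
  if (!any(miss)) {
    out <- calls_from_matrix(m)
    out$imputed <- FALSE
    return(out)
  }
  bad <- !(m %in% c("0", "1", "?", "-"))
  if (any(bad)) abort("unrecognized states in call matrix")
  miss_samples <- rownames(m)[apply(miss, 1L, any)]
  if (!all(miss_samples %in% phy$tip.label)) {
    abort("samples with missing cells must be tips of the guide tree")
  }
  in_tree <- rownames(m) %in% phy$tip.label
  sub <- m[in_tree, , drop = FALSE]
  imp <- fitch_impute(sub, phy, seed = seed, root_state = root_state)
  m[rownames(imp), ] <- imp
  out <- calls_from_matrix(m)
  out$imputed <- as.vector(miss)
  out
}

guide_phylo <- function(tree) {
  if (inherits(tree, "genealogy")) return(tree$tree)
  if (inherits(tree, "ystar_scenario")) return(tree$tree)
  if (inherits(tree, "phylo")) return(tree)
  abort("guide tree must be a genealogy, ystar_scenario, or phylo")
}

# Classic Fitch up/down pass over all sites at once, on binary characters
# encoded as bit sets (1 = {0}, 2 = {1}, 3 = {0,1}). The uppass intersects
# child sets (union on conflict); the downpass assigns each node its
# parent's state whenever the uppass set allows it, so a missing tip inside
# a derived clade inherits the clade's allele. Ambiguity can survive only
# at an unconstrained root, where it is resolved by a seeded uniform draw
# (the rare "imputation doesn't work" case). `m` is a character matrix
# (tips x sites) over {0,1,?,-}; returns the matrix with missing cells
# imputed.
fitch_impute <- function(m, phy, seed = NULL, root_state = "0") {
  idx <- tree_index(phy)
  n_tip <- idx$n_tip
  n_site <- ncol(m)
  ord <- match(phy$tip.label, rownames(m))
  obs <- m[ord, , drop = FALSE]   # rows now in tip-number order
  U <- matrix(3L, idx$n_node, n_site)
  U[seq_len(n_tip), ] <- ifelse(obs == "0", 1L, ifelse(obs == "1", 2L, 3L))
  for (v in idx$postorder) {
    if (v <= n_tip) next
    kids <- idx$children[[v]]
    inter <- rep.int(3L, n_site)
    uni <- rep.int(0L, n_site)
    for (w in kids) {
      inter <- bitwAnd(inter, U[w, ])
      uni <- bitwOr(uni, U[w, ])
    }
    U[v, ] <- ifelse(inter > 0L, inter, uni)
  }
  FS <- matrix(0L, idx$n_node, n_site)
  root <- idx$root
  if (identical(root_state, "0")) {
    FS[root, ] <- ifelse(bitwAnd(U[root, ], 1L) > 0L, 1L, 2L)
  } else {
    FS[root, ] <- U[root, ]
    amb <- FS[root, ] == 3L
    if (any(amb)) {
      with_seed(seed, {
        FS[root, amb] <- ifelse(runif(sum(amb)) < 0.5, 1L, 2L)
      })
    }
  }
  for (v in idx$preorder) {
    p <- idx$parent[v]
    if (p == 0L) next
    keep <- bitwAnd(FS[p, ], U[v, ]) > 0L
    FS[v, ] <- ifelse(keep, FS[p, ], U[v, ])
  }
  out <- obs
  miss <- obs %in% c("?", "-")
  dim(miss) <- dim(obs)
  vals <- ifelse(FS[seq_len(n_tip), , drop = FALSE] == 1L, "0", "1")
  out[miss] <- vals[miss]
  rownames(out) <- phy$tip.label
  out2 <- out[match(rownames(m), rownames(out)), , drop = FALSE]
  rownames(out2) <- rownames(m)
  out2
}
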