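# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# random stream. seed = NULL means "use the ambient stream".
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic per-stage child seed derived from one master seed, kept
# inside 32-bit integer range.
child_seed <- function(seed, stage) {
  if (is.null(seed)) return(NULL)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

# Index structure for an ape::phylo tree reused by several modules.
tree_index <- function(phy) {
  stopifnot(inherits(phy, "phylo"))
  n_tip <- length(phy$tip.label)
  n_node <- n_tip + phy$Nnode
  parent <- integer(n_node)
  parent[phy$edge[, 2L]] <- phy$edge[, 1L]
  children <- vector("list", n_node)
  for (i in seq_len(nrow(phy$edge))) {
    p <- phy$edge[i, 1L]
    children[[p]] <- c(children[[p]], phy$edge[i, 2L])
  }
  root <- n_tip + 1L
  # postorder over nodes (children before parents)
  po <- integer(0)
  stack <- root
  while (length(stack)) {
    v <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    po <- c(po, v)
    stack <- c(stack, children[[v]])
  }
  po <- rev(po)
  tips_under <- vector("list", n_node)
  for (v in po) {
    if (v <= n_tip) {
      tips_under[[v]] <- v
    } else {
      tips_under[[v]] <- unlist(lapply(children[[v]], function(w) tips_under[[w]]))
    }
  }
  list(
    n_tip = n_tip, n_node = n_node, root = root, parent = parent,
    children = children, postorder = po, preorder = rev(po),
    tips_under = tips_under
  )
}

# Root-to-node path length (sum of edge weights) for every node.
node_depths <- function(phy) {
  ape::node.depth.edgelength(phy)
}

greek_letters <- c(
  "α", "β", "γ", "δ", "ε", "ζ", "η",
  "θ", "ι", "κ", "λ", "μ", "ν", "ξ",
  "ο", "π", "ρ", "σ", "τ", "υ", "φ",
  "χ", "ψ", "ω"
)

provenance_header <- function(what, params = list()) {
  kv <- vapply(
    names(params),
    function(k) paste0(k, "=", paste(format(params[[k]], digits = 15), collapse = ",")),
    ""
  )
  c(
    sprintf("# ystar %s: %s", as.character(packageVersion("ystar")), what),
    if (length(kv)) paste0("# ", kv)
  )
}
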