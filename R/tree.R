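#' @title Genealogy objects
#' @description A `genealogy` is a rooted tree whose branch lengths are
#' integer substitution counts, together with the mapping of every placed
#' site to its branch and a report of sites that could not be placed once
#' (homoplasy). It is the output of [build_tree()] and the substrate of the
#' clock and expansion modules.
#' @param tree [ape::phylo] with `edge.length` = substitution counts.
#' @param site_map Tibble `site`, `node` (child node of the carrying edge),
#'   `edge` (row of `tree$edge`), `recurrent`.
#' @param conflicts Tibble of homoplasic sites (`site`, `carriers`,
#'   `n_placements`).
#' @param root_sites Character vector of sites carried by every sample
#'   (placed on the root stem).
#' @return An object of class `genealogy`.
#' @export
genealogy <- function(tree, site_map = NULL, conflicts = NULL,
                      root_sites = character()) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length))
  if (any(tree$edge.length < 0)) abort("branch substitution counts must be >= 0")
  structure(
    list(
      tree = tree,
      site_map = site_map %||% tibble::tibble(
        site = character(), node = integer(), edge = integer(),
        recurrent = logical()
      ),
      conflicts = conflicts %||% tibble::tibble(
        site = character(), carriers = character(), n_placements = integer()
      ),
      root_sites = root_sites
    ),
    class = "genealogy"
  )
}

#' @export
print.genealogy <- function(x, ...) {
  cat(sprintf(
    "<genealogy> %d tips, %d substitutions on %d branches (%d homoplasic sites)\n",
    length(x$tree$tip.label), round(sum(x$tree$edge.length)),
    nrow(x$tree$edge), length(unique(x$conflicts$site))
  ))
  invisible(x)
}

#' @export
#' @method as.phylo genealogy
as.phylo.genealogy <- function(x, ...) x$tree

as_binary_matrix <- function(x) {
  m <- if (is.matrix(x)) x else calls_matrix(normalize_curation_states(x))
  if (!all(m %in% c("0", "1"))) {
    abort("tree building needs a complete binary (0/1) matrix; impute first")
  }
  storage.mode(m) <- "character"
  m
}

site_patterns <- function(m) {
  g <- m == "1"
  key <- vapply(seq_len(ncol(m)), function(j) {
    rawToChar(as.raw(as.integer(g[, j]) + 48L))
  }, "")
  split(seq_len(ncol(m)), key)
}

# nested-or-disjoint test between one candidate pattern and accepted columns
compatible_with <- function(p, P) {
  if (ncol(P) == 0L) return(TRUE)
  n11 <- as.vector(crossprod(P, p))
  sp <- sum(p)
  sq <- colSums(P)
  all(n11 == 0 | n11 == sp | n11 == sq)
}

#' List incompatible site pairs (rooted three-gamete test)
#'
#' In the rooted setting (ancestral state 0 known) two binary sites are
#' compatible with a common perfect phylogeny exactly when their carrier
#' sets are nested or disjoint. This returns every violating pair; an empty
#' result certifies that a perfect phylogeny exists.
#'
#' @param x Complete binary call matrix (long tibble or character matrix).
#' @return Tibble with columns `site_a`, `site_b`.
#' @examples
#' m <- matrix(c("1","1","0", "0","1","1"), nrow = 3,
#'             dimnames = list(c("A","B","C"), c("F00001","F00002")))
#' check_compatibility(m)
#' @export
check_compatibility <- function(x) {
  m <- as_binary_matrix(x)
  pats <- site_patterns(m)
  keys <- names(pats)
  u <- length(keys)
  P <- vapply(keys, function(k) utf8ToInt(k) == 49L, logical(nrow(m)))
  if (!is.matrix(P)) P <- matrix(P, nrow = nrow(m))
  sizes <- colSums(P)
  out <- list()
  if (u >= 2L) {
    X <- crossprod(P)
    for (a in seq_len(u - 1L)) {
      for (b in seq((a + 1L), u)) {
        n11 <- X[a, b]
        if (!(n11 == 0 || n11 == sizes[a] || n11 == sizes[b])) {
          out[[length(out) + 1L]] <- expand.grid(
            site_a = colnames(m)[pats[[a]]],
            site_b = colnames(m)[pats[[b]]],
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  if (!length(out)) {
    return(tibble::tibble(site_a = character(), site_b = character()))
  }
  res <- dplyr::bind_rows(out)
  swap <- res$site_a > res$site_b
  tmp <- res$site_a[swap]; res$site_a[swap] <- res$site_b[swap]; res$site_b[swap] <- tmp
  dplyr::arrange(tibble::as_tibble(res), .data$site_a, .data$site_b)
}

#' Build the rooted perfect phylogeny from a binary matrix
#'
#' Reconstructs the maximum-parsimony tree of a complete binary matrix in
#' the rooted, ancestral-state-0 setting. When all sites are pairwise
#' compatible the result is the unique perfect phylogeny: clades are exactly
#' the carrier sets, every site sits on the branch subtending its carriers,
#' and branch lengths equal per-branch substitution counts. Incompatible
#' sites are resolved greedily: carrier patterns are accepted in decreasing
#' order of supporting-site count (then carrier count, then smallest site
#' ID), and a rejected pattern's sites are placed recurrently on the minimal
#' set of accepted clades covering their carriers, flagged in the conflict
#' report for curation. Multifurcations are kept as such.
#'
#' @param x Complete binary call matrix (long tibble or character matrix).
#' @return A [genealogy()].
#' @examples
#' m <- matrix(
#'   c("1","0","0","0",  "0","1","0","0",  "1","1","0","0",  "1","1","1","0"),
#'   nrow = 4, dimnames = list(LETTERS[1:4], sprintf("F%05d", 1:4))
#' )
#' gen <- build_tree(m)
#' ape::write.tree(gen$tree)
#' @export
build_tree <- function(x) {
  m <- as_binary_matrix(x)
  n <- nrow(m)
  if (n < 2L) abort("tree building needs at least 2 samples")
  samples <- rownames(m)
  sites <- colnames(m)
  g <- m == "1"
  carriers_n <- colSums(g)

  root_sites <- sites[carriers_n == n]
  seg <- which(carriers_n > 0L & carriers_n < n)

  pats <- site_patterns(m[, seg, drop = FALSE])
  keys <- names(pats)
  pats <- lapply(pats, function(ix) seg[ix])
  u <- length(keys)
  P <- if (u) vapply(keys, function(k) utf8ToInt(k) == 49L, logical(n)) else
    matrix(FALSE, n, 0L)
  support <- lengths(pats)
  sizes <- if (u) colSums(P) else integer(0)
  first_site <- vapply(pats, function(ix) min(sites[ix]), "")
  ord <- order(-support, -sizes, first_site)

  accepted <- integer(0)
  rejected <- integer(0)
  for (j in ord) {
    if (compatible_with(P[, j], P[, accepted, drop = FALSE])) {
      accepted <- c(accepted, j)
    } else {
      rejected <- c(rejected, j)
    }
  }

  # laminar family of accepted carrier sets -> rooted tree
  acc_sets <- lapply(accepted, function(j) which(P[, j]))
  acc_support <- support[accepted]
  internal_ix <- which(lengths(acc_sets) >= 2L)      # clades needing a node
  clade_sets <- acc_sets[internal_ix]
  clade_support <- acc_support[internal_ix]
  n_internal <- length(clade_sets) + 1L              # + root
  n_node <- n + n_internal

  # parent of each clade / tip = smallest strict superset in the laminar family
  csizes <- lengths(clade_sets)
  ordc <- order(csizes)
  parent_of_clade <- integer(length(clade_sets))     # 0 = root
  for (a in ordc) {
    cand <- 0L; cand_size <- n + 1L
    for (b in seq_along(clade_sets)) {
      if (b == a || csizes[b] <= csizes[a]) next
      if (all(clade_sets[[a]] %in% clade_sets[[b]]) && csizes[b] < cand_size) {
        cand <- b; cand_size <- csizes[b]
      }
    }
    parent_of_clade[a] <- cand
  }
  parent_of_tip <- integer(n)                        # 0 = root
  for (tip in seq_len(n)) {
    cand <- 0L; cand_size <- n + 1L
    for (b in seq_along(clade_sets)) {
      if (tip %in% clade_sets[[b]] && csizes[b] < cand_size) {
        cand <- b; cand_size <- csizes[b]
      }
    }
    parent_of_tip[tip] <- cand
  }

  # terminal-edge counts from singleton accepted patterns
  tip_count <- integer(n)
  singleton_ix <- which(lengths(acc_sets) == 1L)
  for (si in singleton_ix) tip_count[acc_sets[[si]][1L]] <- acc_support[si]

  # assemble edges in preorder; clade index 0 is the root
  kids_clades <- split(seq_along(clade_sets), factor(parent_of_clade, levels = 0:length(clade_sets)))
  kids_tips <- split(seq_len(n), factor(parent_of_tip, levels = 0:length(clade_sets)))
  node_id <- integer(length(clade_sets))             # ape ids for clades
  root_id <- n + 1L
  next_id <- n + 2L
  edges <- matrix(0L, 0L, 2L)
  counts <- numeric(0)
  edge_child_clade <- integer(0)                     # clade index of child (0 = tip)
  stack <- list(list(clade = 0L, id = root_id))
  while (length(stack)) {
    fr <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    ci <- fr$clade
    key <- as.character(ci)
    tips_here <- kids_tips[[key]]
    clades_here <- kids_clades[[key]]
    # children ordered by smallest member tip for determinism
    child_list <- c(
      lapply(tips_here, function(t) list(type = "tip", ix = t, min_tip = t)),
      lapply(clades_here, function(cc) list(type = "clade", ix = cc,
                                            min_tip = min(clade_sets[[cc]])))
    )
    child_list <- child_list[order(vapply(child_list, `[[`, 0, "min_tip"))]
    for (ch in child_list) {
      if (ch$type == "tip") {
        edges <- rbind(edges, c(fr$id, ch$ix))
        counts <- c(counts, tip_count[ch$ix])
        edge_child_clade <- c(edge_child_clade, 0L)
      } else {
        id <- next_id; next_id <- next_id + 1L
        node_id[ch$ix] <- id
        edges <- rbind(edges, c(fr$id, id))
        counts <- c(counts, clade_support[ch$ix])
        edge_child_clade <- c(edge_child_clade, ch$ix)
        stack <- c(stack, list(list(clade = ch$ix, id = id)))
      }
    }
  }
  phy <- structure(
    list(edge = edges, edge.length = counts, Nnode = n_internal,
         tip.label = samples),
    class = "phylo", order = "cladewise"
  )

  # site -> edge map for accepted patterns (plain vectors, one tibble at end)
  edge_of_child <- setNames(seq_len(nrow(edges)), edges[, 2L])
  ms_site <- character(0); ms_node <- integer(0); ms_rec <- logical(0)
  for (k in seq_along(accepted)) {
    j <- accepted[k]
    set <- acc_sets[[k]]
    child <- if (length(set) == 1L) {
      set
    } else {
      node_id[which(vapply(clade_sets, function(s) identical(s, set), TRUE))]
    }
    ms_site <- c(ms_site, sites[pats[[j]]])
    ms_node <- c(ms_node, rep.int(as.integer(child), length(pats[[j]])))
    ms_rec <- c(ms_rec, rep.int(FALSE, length(pats[[j]])))
  }

  # recurrent placement of rejected (homoplasic) patterns
  cf_site <- character(0); cf_carriers <- character(0); cf_np <- integer(0)
  if (length(rejected)) {
    # laminar units available for covering: clades and single tips
    for (j in rejected) {
      remaining <- which(P[, j])
      placements <- integer(0)
      while (length(remaining)) {
        best <- 0L; best_len <- 0L
        for (b in seq_along(clade_sets)) {
          if (csizes[b] > best_len && all(clade_sets[[b]] %in% remaining)) {
            best <- b; best_len <- csizes[b]
          }
        }
        if (best > 0L) {
          child <- node_id[best]
          remaining <- setdiff(remaining, clade_sets[[best]])
        } else {
          child <- remaining[1L]
          remaining <- remaining[-1L]
        }
        placements <- c(placements, child)
      }
      for (child in placements) {
        e <- edge_of_child[[as.character(child)]]
        counts[e] <- counts[e] + length(pats[[j]])
        ms_site <- c(ms_site, sites[pats[[j]]])
        ms_node <- c(ms_node, rep.int(as.integer(child), length(pats[[j]])))
        ms_rec <- c(ms_rec, rep.int(TRUE, length(pats[[j]])))
      }
      cf_site <- c(cf_site, sites[pats[[j]]])
      cf_carriers <- c(cf_carriers,
                       rep.int(paste(samples[which(P[, j])], collapse = ","),
                               length(pats[[j]])))
      cf_np <- c(cf_np, rep.int(length(placements), length(pats[[j]])))
    }
    phy$edge.length <- counts
  }

  site_map <- if (length(ms_site)) {
    ord_s <- order(ms_site)
    tibble::tibble(
      site = ms_site[ord_s], node = ms_node[ord_s],
      edge = as.integer(edge_of_child[as.character(ms_node[ord_s])]),
      recurrent = ms_rec[ord_s]
    )
  } else NULL
  conflicts <- if (length(cf_site)) {
    ord_c <- order(cf_site)
    tibble::tibble(site = cf_site[ord_c], carriers = cf_carriers[ord_c],
                   n_placements = cf_np[ord_c])
  } else NULL
  genealogy(phy, site_map = site_map, conflicts = conflicts,
            root_sites = root_sites)
}

#' Ground-truth genealogy of a simulation
#'
#' Packages the generating scenario's topology with the simulated per-branch
#' mutation counts as a [genealogy()] — the exact answer that inference from
#' the same simulation should recover.
#'
#' @param sim A `ystar_sim` from [simulate_mutations()].
#' @return A [genealogy()].
#' @export
true_genealogy <- function(sim) {
  stopifnot(inherits(sim, "ystar_sim"))
  phy <- sim$scenario$tree
  phy$edge.length <- as.numeric(sim$edge_counts)
  genealogy(
    phy,
    site_map = tibble::tibble(
      site = sim$sites$site, node = as.integer(sim$sites$node),
      edge = sim$sites$edge, recurrent = FALSE
    )
  )
}

#' Root-to-tip substitution counts
#'
#' Sums branch substitution counts along the path from the samples' most
#' recent common ancestor to each tip — the per-lineage molecular-clock
#' reading. Sites carried by every sample (root stem) are excluded, as they
#' predate the MRCA.
#'
#' @param gen A [genealogy()].
#' @param tip Optional tip label(s); default all tips.
#' @return Named numeric vector of counts.
#' @examples
#' m <- matrix(c("1","0", "0","1", "1","1"), nrow = 2,
#'             dimnames = list(c("A","B"), sprintf("F%05d", 1:3)))
#' branch_counts(build_tree(m))
#' @export
branch_counts <- function(gen, tip = NULL) {
  stopifnot(inherits(gen, "genealogy"))
  depth <- node_depths(gen$tree)
  n_tip <- length(gen$tree$tip.label)
  out <- setNames(depth[seq_len(n_tip)], gen$tree$tip.label)
  if (!is.null(tip)) {
    if (!all(tip %in% names(out))) abort("unknown tip label")
    out <- out[tip]
  }
  out
}

#' Write a genealogy as Newick plus site-map / conflict TSVs
#'
#' Branch lengths in the Newick are substitution counts. The companion
#' site-map TSV records each site's carrying branch (child node, ape
#' numbering) and the conflict TSV lists homoplasic sites.
#'
#' @param gen A [genealogy()].
#' @param path Newick path; companions get suffixes `.sites.tsv` and
#'   `.conflicts.tsv`.
#' @return `path`, invisibly.
#' @export
write_genealogy <- function(gen, path) {
  writeLines(ape::write.tree(gen$tree), path)
  write.table(gen$site_map, paste0(path, ".sites.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(gen$conflicts, paste0(path, ".conflicts.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
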