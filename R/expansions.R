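#' Upper confidence bound on a branch's duration
#'
#' One-sided upper `conf` Poisson bound on the mean of a branch that showed
#' `n` substitutions, converted to years. For `n = 0` this is the rule of
#' three: at most ~3 expected substitutions, i.e. at most `3/(mu*L)` years
#' (769 years at the default clock) — the resolution with which an
#' unmutated branch bounds the duration of an expansion.
#'
#' @param n Substitution count(s) on the branch.
#' @param clock A [clock_model()].
#' @param conf One-sided confidence level.
#' @return Years (vectorized over `n`).
#' @examples
#' branch_upper_years(0)   # 769 years
#' branch_upper_years(10)  # far longer
#' @export
branch_upper_years <- function(n, clock = clock_model(), conf = 0.95) {
  qchisq(conf, 2 * n + 2) / 2 / (clock$mu * clock$L)
}

#' Collapse internal branches compatible with a short time window
#'
#' Contracts every internal branch whose substitution count is compatible —
#' at the upper `conf` Poisson bound — with a duration shorter than
#' `max_window_years`, re-attaching its children to its parent. The result
#' makes star-like structures explicit as multifurcations. Root-to-tip path
#' counts are preserved: a contracted branch's count migrates onto each of
#' its child branches (with the default window only zero-count branches
#' collapse, so no count actually moves). Terminal branches are never
#' contracted. Idempotent.
#'
#' @param gen A [genealogy()].
#' @param clock A [clock_model()].
#' @param max_window_years Time window defining "short" (> 0); 1000 years
#'   is the nomenclature default, 500 matches the observed expansions.
#' @param conf One-sided confidence level of the duration bound.
#' @return A [genealogy()] with an attribute `collapsed` (tibble: `node`,
#'   `count`, `upper_years` of each contracted branch).
#' @export
collapse_short_branches <- function(gen, clock = clock_model(),
                                    max_window_years = 1000, conf = 0.95) {
  stopifnot(inherits(gen, "genealogy"))
  if (max_window_years <= 0) abort("max_window_years must be > 0")
  phy <- gen$tree
  n_tip <- length(phy$tip.label)
  idx <- tree_index(phy)
  counts <- phy$edge.length
  child <- phy$edge[, 2L]
  internal_edge <- child > n_tip
  upper <- branch_upper_years(counts, clock, conf)
  drop <- internal_edge & upper < max_window_years

  if (!any(drop)) {
    attr(gen, "collapsed") <- tibble::tibble(
      node = integer(), into = integer(), count = numeric(),
      upper_years = numeric()
    )
    attr(gen, "window_conf") <- conf
    return(gen)
  }

  # contract in preorder: a dropped node's children move to its (surviving)
  # parent, and its incoming count migrates onto each child branch so that
  # root-to-tip path sums are untouched
  kids <- idx$children
  cnt_in <- numeric(idx$n_node)
  cnt_in[child] <- counts
  dead <- rep(FALSE, idx$n_node)
  absorber <- integer(idx$n_node)
  drop_node <- child[drop]
  for (v in idx$preorder) {
    if (v <= n_tip || dead[v]) next
    repeat {
      hit <- kids[[v]][kids[[v]] %in% drop_node]
      if (!length(hit)) break
      for (w in hit) {
        for (u in kids[[w]]) cnt_in[u] <- cnt_in[u] + cnt_in[w]
        kids[[v]] <- c(setdiff(kids[[v]], w), kids[[w]])
        dead[w] <- TRUE
        absorber[w] <- v
      }
    }
  }

  min_tip <- integer(idx$n_node)
  for (v in idx$postorder) {
    if (v <= n_tip) {
      min_tip[v] <- v
    } else if (!dead[v]) {
      min_tip[v] <- min(vapply(kids[[v]], function(w) min_tip[w], 0L))
    }
  }

  # rebuild phylo in preorder, children ordered by smallest descendant tip
  new_id <- integer(idx$n_node)
  new_id[idx$root] <- n_tip + 1L
  next_id <- n_tip + 2L
  edges <- matrix(0L, 0L, 2L)
  lens <- numeric(0)
  stack <- idx$root
  while (length(stack)) {
    v <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    ch <- kids[[v]]
    ch <- ch[order(vapply(ch, function(w) min_tip[w], 0L))]
    for (w in ch) {
      if (w <= n_tip) {
        wid <- w
      } else {
        wid <- next_id
        next_id <- next_id + 1L
        new_id[w] <- wid
        stack <- c(stack, w)
      }
      edges <- rbind(edges, c(new_id[v], wid))
      lens <- c(lens, cnt_in[w])
    }
  }
  new_phy <- structure(
    list(edge = edges, edge.length = lens,
         Nnode = as.integer(next_id - 1L - n_tip), tip.label = phy$tip.label),
    class = "phylo", order = "cladewise"
  )

  # follow chains of contracted nodes down to surviving descendants
  live_targets <- function(v) {
    if (v <= n_tip || !dead[v]) return(v)
    unlist(lapply(idx$children[[v]], live_targets))
  }
  live_absorber <- function(v) {
    while (dead[v]) v <- absorber[v]
    v
  }
  collapsed <- tibble::tibble(
    node = child[drop],
    into = as.integer(new_id[vapply(child[drop], live_absorber, 0L)]),
    count = counts[drop],
    upper_years = upper[drop]
  )

  # sites of contracted branches are re-booked on each child branch,
  # mirroring the count migration
  sm <- gen$site_map
  if (nrow(sm)) {
    edge_of_child <- setNames(seq_len(nrow(edges)), edges[, 2L])
    rows <- lapply(seq_len(nrow(sm)), function(i) {
      v <- sm$node[i]
      targets <- vapply(live_targets(v), function(w) {
        if (w <= n_tip) w else as.integer(new_id[w])
      }, 0L)
      tibble::tibble(
        site = sm$site[i], node = as.integer(targets),
        edge = as.integer(edge_of_child[as.character(targets)]),
        recurrent = sm$recurrent[i] | length(targets) > 1L
      )
    })
    sm <- dplyr::bind_rows(rows)
  }
  out <- genealogy(new_phy, site_map = sm, conflicts = gen$conflicts,
                   root_sites = gen$root_sites)
  attr(out, "collapsed") <- collapsed
  attr(out, "window_conf") <- conf
  out
}

#' Detect star-like expansions
#'
#' A star-like expansion is a node from which at least `min_lineages`
#' lineages radiate within a time window too short for shared mutations to
#' accumulate — the signature of rapid growth of one paternal line. After
#' collapsing short internal branches (see [collapse_short_branches()]),
#' every internal node whose child count reaches `min_lineages` is
#' reported, with its clock age and the upper bound on the expansion
#' window. Resolving a window under 1000 years requires more than 1 Mbp of
#' analyzed sequence; a warning is issued when the clock offers less.
#'
#' @param gen A [genealogy()].
#' @param clock A [clock_model()].
#' @param min_lineages Minimum child lineages (the nomenclature rule uses
#'   5).
#' @param max_window_years Collapse window in years.
#' @param conf Confidence level for window bounds and ages.
#' @param method Age CI method, see [node_age()].
#' @param collapse Collapse short branches first? (Set `FALSE` if `gen` is
#'   already collapsed.)
#' @return A `star_report` tibble: `node`, `k` (lineage count), `n_tips`,
#'   `mean_count`, `age_years`, `ci_low`, `ci_high`, `window_years`,
#'   `name` (NA until [assign_names()]), plus the collapsed genealogy as
#'   attribute `genealogy`.
#' @examples
#' sim <- simulate_mutations(star_scenario(6, 5400, 30000),
#'                           seq_params(seed = 7))
#' stars <- detect_stars(true_genealogy(sim))
#' stars$k
#' @export
detect_stars <- function(gen, clock = clock_model(), min_lineages = 5,
                         max_window_years = 1000, conf = 0.95,
                         method = "normal", collapse = TRUE) {
  stopifnot(inherits(gen, "genealogy"))
  if (clock$L <= 1e6) {
    warn(paste(
      "analyzed length is at or below 1 Mbp: zero-substitution branches only",
      "bound expansion windows above 1000 years; star calls are unreliable"
    ))
  }
  g2 <- if (collapse) {
    collapse_short_branches(gen, clock, max_window_years, conf)
  } else {
    gen
  }
  collapsed <- attr(g2, "collapsed") %||%
    tibble::tibble(node = integer(), into = integer(), count = numeric(),
                   upper_years = numeric())
  phy <- g2$tree
  n_tip <- length(phy$tip.label)
  deg <- table(factor(phy$edge[, 1L], levels = n_tip + seq_len(phy$Nnode)))
  star_nodes <- as.integer(names(deg))[deg >= min_lineages]
  base_window <- branch_upper_years(0, clock, conf)
  rows <- lapply(star_nodes, function(v) {
    age <- node_age(g2, v, clock, method = method, conf = conf)
    # window: the widest duration bound among branches contracted into v,
    # or the zero-count resolution bound if v was natively multifurcating
    here <- collapsed$upper_years[collapsed$into == v]
    w <- max(base_window, here)
    dplyr::mutate(age, k = as.integer(deg[as.character(v)]),
                  window_years = w, name = NA_character_)
  })
  out <- if (length(rows)) {
    dplyr::bind_rows(rows) |>
      dplyr::select("node", "k", "n_tips", "mean_count", "age_years",
                    "ci_low", "ci_high", "window_years", "name") |>
      dplyr::arrange(dplyr::desc(.data$n_tips), .data$age_years, .data$node)
  } else {
    tibble::tibble(
      node = integer(), k = integer(), n_tips = integer(),
      mean_count = numeric(), age_years = numeric(), ci_low = numeric(),
      ci_high = numeric(), window_years = numeric(), name = character()
    )
  }
  structure(out, class = c("star_report", class(out)),
            genealogy = g2, clock = clock,
            min_lineages = min_lineages, max_window_years = max_window_years)
}

#' Name star-like expansions with Greek letters
#'
#' The nomenclature rule: an important star-like expansion (at least five
#' lineages within a short window, resolved by long-range sequencing) is
#' named by the capital letter of its first-class haplogroup followed by a
#' lowercase Greek letter, bound to the expansion node itself rather than
#' to any defining SNP. Letters are assigned in a stable, documented order:
#' decreasing clade size (tip count), then increasing age, then node
#' number. Downstream lineages append YCC-style alternating numbers and
#' letters after the Greek letter (see [lineage_name()]).
#'
#' @param stars A `star_report` from [detect_stars()].
#' @param haplogroup_letter Capital haplogroup letter prefix.
#' @return The `star_report` with `name` filled (e.g. `"Oα"`, `"Oβ"`).
#' @examples
#' # three stars under haplogroup O become Oα, Oβ, Oγ
#' @export
assign_names <- function(stars, haplogroup_letter = "O") {
  stopifnot(inherits(stars, "star_report"))
  if (nrow(stars) > length(greek_letters)) {
    abort("more star expansions than Greek letters; refine detection thresholds")
  }
  ord <- order(-stars$n_tips, stars$age_years, stars$node)
  stars$name[ord] <- paste0(haplogroup_letter, greek_letters[seq_len(nrow(stars))])
  stars
}

#' Label a lineage downstream of a named expansion
#'
#' @param star_name Name of the expansion (e.g. `"Oα"`).
#' @param path Vector of YCC-style steps (numbers and letters) below the
#'   expansion node.
#' @return Character label such as `"Oα1a1"`.
#' @examples
#' lineage_name("Oα", c(1, "a", 1))
#' @export
lineage_name <- function(star_name, path) {
  paste0(star_name, paste(path, collapse = ""))
}

#' Combined descent fraction of disjoint clades
#'
#' Sums survey frequencies (percent of a reference population) of clades
#' declared disjoint — e.g. the shares of a population descending from
#' each detected expansion.
#'
#' @param clade_frequencies Numeric vector of percentages in `[0, 100]`.
#' @return The combined percentage.
#' @examples
#' descent_fraction(c(16, 11, 14))  # 41
#' @export
descent_fraction <- function(clade_frequencies) {
  if (!length(clade_frequencies)) return(0)
  if (any(clade_frequencies < 0 | clade_frequencies > 100)) {
    abort("clade frequencies must be percentages in [0, 100]")
  }
  total <- sum(clade_frequencies)
  if (total > 100) {
    abort("combined frequency exceeds 100%: clades cannot be disjoint")
  }
  total
}
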