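# broom-style accessors for the package's result objects.

#' Tidy a genealogy into its edge table
#'
#' @param x A [genealogy()].
#' @param ... Unused.
#' @return Tibble with one row per branch: `parent`, `node`, `count`,
#'   `n_sites`, `is_tip`, `label`.
#' @method tidy genealogy
#' @export
tidy.genealogy <- function(x, ...) {
  n_tip <- length(x$tree$tip.label)
  child <- x$tree$edge[, 2L]
  n_sites <- integer(nrow(x$tree$edge))
  if (nrow(x$site_map)) {
    tab <- table(x$site_map$edge)
    n_sites[as.integer(names(tab))] <- as.integer(tab)
  }
  tibble::tibble(
    parent = x$tree$edge[, 1L],
    node = child,
    count = x$tree$edge.length,
    n_sites = n_sites,
    is_tip = child <= n_tip,
    label = ifelse(child <= n_tip, x$tree$tip.label[pmin(child, n_tip)],
                   NA_character_)
  )
}

#' @rdname tidy.genealogy
#' @method glance genealogy
#' @export
glance.genealogy <- function(x, ...) {
  tibble::tibble(
    n_tips = length(x$tree$tip.label),
    n_internal = x$tree$Nnode,
    n_substitutions = sum(x$tree$edge.length),
    n_sites_placed = dplyr::n_distinct(x$site_map$site),
    n_homoplasic = dplyr::n_distinct(x$conflicts$site),
    n_root_sites = length(x$root_sites)
  )
}

#' Tidy / summarize a node-dating table
#'
#' @param x A `clock_dating` from [date_nodes()].
#' @param ... Unused.
#' @return `tidy()` returns the dating tibble; `glance()` one row with the
#'   clock parameters and the root age.
#' @method tidy clock_dating
#' @export
tidy.clock_dating <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @rdname tidy.clock_dating
#' @method glance clock_dating
#' @export
glance.clock_dating <- function(x, ...) {
  clock <- attr(x, "clock")
  root <- x[which.max(x$n_tips), ]
  tibble::tibble(
    n_nodes = nrow(x), mu = clock$mu, L = clock$L,
    years_per_substitution = clock$years_per_substitution,
    method = root$method, conf = root$conf,
    root_age_years = root$age_years,
    root_ci_low = root$ci_low, root_ci_high = root$ci_high
  )
}

#' Tidy / summarize a star-expansion report
#'
#' @param x A `star_report` from [detect_stars()].
#' @param ... Unused.
#' @method tidy star_report
#' @export
tidy.star_report <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @rdname tidy.star_report
#' @method glance star_report
#' @export
glance.star_report <- function(x, ...) {
  tibble::tibble(
    n_stars = nrow(x),
    total_lineages = sum(x$k),
    min_lineages = attr(x, "min_lineages"),
    max_window_years = attr(x, "max_window_years"),
    youngest_age = if (nrow(x)) min(x$age_years) else NA_real_,
    oldest_age = if (nrow(x)) max(x$age_years) else NA_real_
  )
}

#' Tidy an outgroup rate recalibration
#'
#' @param x An `outgroup_rate` from [rate_from_outgroup()].
#' @param ... Unused.
#' @method tidy outgroup_rate
#' @export
tidy.outgroup_rate <- function(x, ...) {
  tibble::tibble(
    implied_rate = x$implied_rate,
    comparable_fraction = x$comparable_fraction,
    age_scale = x$age_scale
  )
}
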