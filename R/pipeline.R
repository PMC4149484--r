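#' Configuration of an end-to-end run
#'
#' A run is fully determined by its configuration (plus any input files):
#' one master seed drives all stages through derived child seeds. Defaults
#' are the study conditions throughout: the three-star 49-tip panel, 6x
#' mean coverage, the published calling thresholds, the 1e-9 /bp/yr clock
#' over 3.9 Mbp, and the >= 5 lineages / 1000-year star rule.
#'
#' @param seed Master integer seed.
#' @param scenario A [scenario()]; default [multi_star_scenario()].
#' @param params A [seq_params()] (its `seed` is overridden by `seed`).
#' @param policy A [site_filter_policy()].
#' @param clock A [clock_model()].
#' @param min_lineages,max_window_years Star detection thresholds.
#' @param haplogroup_letter Prefix for expansion names.
#' @param ci_method Age CI method ("normal", "exact", "gamma").
#' @param conf Confidence level.
#' @param simulate Simulate inputs? If `FALSE`, `counts` must be supplied
#'   to [run_pipeline()].
#' @param out_dir Optional directory for output files.
#' @return A `run_config` list.
#' @examples
#' cfg <- run_config(seed = 1)
#' @export
run_config <- function(seed = 1, scenario = NULL, params = seq_params(),
                       policy = site_filter_policy(), clock = clock_model(),
                       min_lineages = 5, max_window_years = 1000,
                       haplogroup_letter = "O", ci_method = "normal",
                       conf = 0.95, simulate = TRUE, out_dir = NULL) {
  params$seed <- seed
  structure(
    list(seed = seed, scenario = scenario, params = params, policy = policy,
         clock = clock, min_lineages = min_lineages,
         max_window_years = max_window_years,
         haplogroup_letter = haplogroup_letter, ci_method = ci_method,
         conf = conf, simulate = simulate, out_dir = out_dir),
    class = "run_config"
  )
}

#' Run the full analysis chain
#'
#' Orchestrates simulate → call → filter → tree → impute → re-tree →
#' date → detect/name stars as one reproducible run. The guide tree for
#' imputation is built from the unimputed definite calls, then the final
#' tree is rebuilt from the completed matrix. Identical configuration and
#' inputs give identical outputs.
#'
#' @param config A [run_config()].
#' @param counts Optional allele-count tibble (required when
#'   `config$simulate` is `FALSE`).
#' @return A `run_report` list: `config`, `scenario`, `sim`, `counts`,
#'   `calls` (filtered, imputed), `genealogy`, `dating`, `stars`, and a
#'   `log` tibble of per-stage record counts. If `config$out_dir` is set,
#'   the call matrix TSV, dated Newick, star report TSV, and a JSON run
#'   report are written there.
#' @examples
#' \donttest{
#' rep <- run_pipeline(run_config(seed = 1,
#'   scenario = star_scenario(6, 5400, 30000, n_background = 4),
#'   params = seq_params(depth_mean = 8)))
#' rep$stars$name
#' }
#' @export
run_pipeline <- function(config = run_config(), counts = NULL) {
  stopifnot(inherits(config, "run_config"))
  log <- list()
  note <- function(stage, n_in, n_out, detail = "") {
    log[[length(log) + 1L]] <<- tibble::tibble(
      stage = stage, records_in = n_in, records_out = n_out, detail = detail
    )
  }

  scn <- config$scenario
  sim <- NULL
  if (config$simulate) {
    scn <- scn %||% multi_star_scenario()
    sim <- simulate_mutations(scn, config$params)
    note("simulate_mutations", length(scn$tree$tip.label), nrow(sim$sites),
         "segregating sites")
    counts <- simulate_reads(sim, config$params)
    note("simulate_reads", nrow(sim$sites), nrow(counts), "cells")
  } else if (is.null(counts)) {
    abort(paste(
      "simulation is disabled and no allele counts were supplied;",
      "provide `counts` or enable `simulate` in the config"
    ))
  }

  calls <- call_genotypes(counts, config$policy)
  calls <- apply_private_filter(calls, counts, config$policy)
  note("call_genotypes", nrow(counts), nrow(calls),
       sprintf("definite calls: %d", sum(calls$state %in% c("0", "1"))))

  filtered <- filter_sites(calls, config$policy)
  note("filter_sites", dplyr::n_distinct(calls$site),
       dplyr::n_distinct(filtered$site), "sites retained")

  # guide tree from definite carriers, then impute and rebuild
  m0 <- calls_matrix(filtered)
  m0[m0 %in% c("?", "-")] <- "0"
  guide <- build_tree(m0)
  imputed <- impute_missing(filtered, guide,
                            seed = child_seed(config$seed, "impute"))
  note("impute_missing", sum(filtered$state %in% c("?", "-")),
       sum(imputed$imputed), "cells imputed")

  gen <- build_tree(dplyr::select(imputed, -"imputed"))
  note("build_tree", dplyr::n_distinct(imputed$site),
       nrow(gen$site_map), sprintf("homoplasic sites: %d",
                                   dplyr::n_distinct(gen$conflicts$site)))

  dating <- date_nodes(gen, config$clock, method = config$ci_method,
                       conf = config$conf)
  note("date_nodes", gen$tree$Nnode, nrow(dating), "internal nodes dated")

  stars <- detect_stars(gen, config$clock,
                        min_lineages = config$min_lineages,
                        max_window_years = config$max_window_years,
                        conf = config$conf, method = config$ci_method)
  stars <- assign_names(stars, config$haplogroup_letter)
  note("detect_stars", gen$tree$Nnode, nrow(stars),
       paste(stars$name, collapse = ","))

  report <- structure(
    list(config = config, scenario = scn, sim = sim, counts = counts,
         calls = imputed, genealogy = gen, dating = dating, stars = stars,
         log = dplyr::bind_rows(log)),
    class = "run_report"
  )
  if (!is.null(config$out_dir)) write_run_report(report, config$out_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  print(x$log)
  invisible(x)
}

write_run_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- report$config
  prov <- list(seed = cfg$seed, mu = cfg$clock$mu, L = cfg$clock$L,
               depth_mean = cfg$params$depth_mean,
               error_rate = cfg$params$error_rate)
  write_call_matrix(dplyr::select(report$calls, -dplyr::any_of("imputed")),
                    file.path(dir, "call_matrix.tsv"), params = prov)
  write_dated_newick(report$genealogy, report$dating,
                     file.path(dir, "genealogy_dated.nwk"))
  stars <- tibble::as_tibble(report$stars)
  con <- file(file.path(dir, "stars.tsv"), "w")
  writeLines(provenance_header("star-like expansions", prov), con)
  suppressWarnings(write.table(stars, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  close(con)
  jsonlite::write_json(
    list(
      version = as.character(packageVersion("ystar")),
      seed = cfg$seed,
      stages = report$log,
      stars = stars,
      dated_nodes = tibble::as_tibble(report$dating)
    ),
    file.path(dir, "run_report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(dir)
}

#' Write a packaged toy dataset
#'
#' Generates the small fixture set used by examples and tests: a reduced
#' star-panel scenario with its allele counts (a shortened analyzable
#' length keeps files small), and a toy bait-design genome in which a
#' central block of the target is duplicated on an off-target sequence.
#' All files are plain text with provenance headers.
#'
#' @param seed Integer seed (default 1, recorded in the headers).
#' @param dir Output directory.
#' @return Named character vector of the files written, invisibly.
#' @export
make_fixtures <- function(seed = 1, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  scn <- star_scenario(8, 5400, 30000, n_background = 4)
  files <- c(scenario = file.path(dir, "star_scenario.nwk"))
  write_scenario(scn, files[["scenario"]], params = list(seed = seed))
  par <- seq_params(L = 2e5, depth_mean = 8, error_rate = 1e-3, seed = seed)
  sim <- simulate_mutations(scn, par)
  counts <- simulate_reads(sim, par)
  files[["counts"]] <- file.path(dir, "star_counts.tsv")
  write_counts(counts, files[["counts"]],
               params = list(seed = seed, L = par$L, mu = par$mu,
                             depth_mean = par$depth_mean,
                             error_rate = par$error_rate))
  # toy bait genome: 1.2 kb target with its 300-500 bp block repeated on an
  # off-target sequence
  g <- with_seed(child_seed(seed, "baits"), {
    tgt <- paste(sample(c("A", "C", "G", "T"), 1200, TRUE), collapse = "")
    other <- paste(sample(c("A", "C", "G", "T"), 800, TRUE), collapse = "")
    dup <- substring(tgt, 301, 500)
    c(chrY = tgt, chrOther = paste0(substring(other, 1, 400), dup,
                                    substring(other, 401, 800)))
  })
  files[["genome"]] <- file.path(dir, "bait_toy_genome.fa")
  writeLines(as.vector(rbind(paste0(">", names(g)), g)), files[["genome"]])
  invisible(files)
}
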