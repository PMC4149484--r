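#' Sequencing-experiment parameters
#'
#' Parameters of the mutation and read-count model. Defaults are the study
#' conditions of a pooled-capture NRY panel: L = 3.9 Mbp of analyzable
#' sequence, a strict substitution rate of 1e-9 per bp per year (one
#' substitution per 256.4 years over the panel), mean per-cell coverage of
#' 6x, and a small symmetric per-read miscall rate.
#'
#' @param L Analyzed sequence length in bp (> 0).
#' @param mu Substitution rate per bp per year (> 0).
#' @param depth_mean Mean per-sample, per-site sequencing depth (>= 0).
#' @param error_rate Per-read, per-site probability of reporting the other
#'   allele (0 <= error_rate < 1).
#' @param seed Master integer seed; per-stage child seeds are derived from it
#'   deterministically. NULL uses the ambient RNG stream.
#' @return A `seq_params` list.
#' @examples
#' seq_params(depth_mean = 6, error_rate = 1e-3, seed = 1)
#' @export
seq_params <- function(L = 3.9e6, mu = 1e-9, depth_mean = 6,
                       error_rate = 0, seed = NULL) {
  stopifnot(L > 0, mu > 0, depth_mean >= 0, error_rate >= 0, error_rate < 1)
  structure(
    list(L = L, mu = mu, depth_mean = depth_mean,
         error_rate = error_rate, seed = seed),
    class = "seq_params"
  )
}

#' Drop Poisson mutations on a genealogy (infinite sites)
#'
#' Each branch of duration `dt` years receives K ~ Poisson(mu * L * dt)
#' mutations; all mutations across the tree land on distinct positions in
#' `[0, L)` (the infinite-sites contract — no site is hit twice, no
#' back-mutation). A tip carries a mutation exactly when the mutated branch
#' lies on its root path. Site IDs are F-numbered in position order,
#' following the panel convention of naming newly discovered SNPs.
#'
#' @param scn A [scenario()].
#' @param params A [seq_params()]; the child seed for this stage is derived
#'   from `params$seed`.
#' @return An object of class `ystar_sim`: list with `scenario`, `params`,
#'   `sites` (tibble: `site`, `position` 0-based, `edge` row index into
#'   `scenario$tree$edge`, `node` child node of that edge), `genotypes`
#'   (integer tips x sites matrix of 0/1), and `edge_counts` (mutations per
#'   edge).
#' @examples
#' sim <- simulate_mutations(star_scenario(5, 5400, 20000),
#'                           seq_params(seed = 1))
#' nrow(sim$sites)
#' @export
simulate_mutations <- function(scn, params = seq_params()) {
  stopifnot(inherits(scn, "ystar_scenario"), inherits(params, "seq_params"))
  phy <- scn$tree
  idx <- tree_index(phy)
  lam <- params$mu * params$L * phy$edge.length
  with_seed(child_seed(params$seed, "mutations"), {
    k <- rpois(length(lam), lam)
    total <- sum(k)
    if (total > params$L) {
      abort("more mutations than available positions; degenerate parameters")
    }
    pos <- sort(sample.int(params$L, total)) - 1L  # distinct, 0-based
    # assign edges, then order sites by position so F-names follow coordinates
    edge_of <- rep.int(seq_along(k), k)
    if (total > 1L) edge_of <- edge_of[sample.int(total)]  # decouple position from edge
    sites <- tibble::tibble(
      site = sprintf("F%05d", seq_len(total)),
      position = pos,
      edge = edge_of,
      node = phy$edge[edge_of, 2L]
    )
    g <- matrix(0L, nrow = idx$n_tip, ncol = total,
                dimnames = list(phy$tip.label, sites$site))
    for (e in unique(edge_of)) {
      tips <- idx$tips_under[[phy$edge[e, 2L]]]
      g[tips, which(edge_of == e)] <- 1L
    }
    structure(
      list(scenario = scn, params = params, sites = sites,
           genotypes = g, edge_counts = k),
      class = "ystar_sim"
    )
  })
}

#' @export
print.ystar_sim <- function(x, ...) {
  cat(sprintf(
    "<ystar_sim> %d tips x %d segregating sites (mu=%g, L=%g)\n",
    nrow(x$genotypes), ncol(x$genotypes), x$params$mu, x$params$L
  ))
  invisible(x)
}

#' Simulate per-cell read counts from haplotypes
#'
#' Emulates the pooled-capture coverage regime: each sample x site cell draws
#' depth ~ Poisson(`depth_mean`); each read reports the sample's true allele
#' with probability `1 - error_rate` and the other allele otherwise
#' (symmetric biallelic error). Cells with depth 0 become the no-coverage
#' state downstream.
#'
#' @param haplotypes A `ystar_sim` from [simulate_mutations()], or an integer
#'   0/1 matrix (samples x sites, dimnames required).
#' @param params A [seq_params()].
#' @return A tibble with columns `sample`, `site`, `ref_count`, `alt_count`
#'   (one row per cell).
#' @examples
#' sim <- simulate_mutations(star_scenario(5, 5400, 20000),
#'                           seq_params(seed = 1))
#' counts <- simulate_reads(sim, seq_params(depth_mean = 10, seed = 1))
#' counts
#' @export
simulate_reads <- function(haplotypes, params = seq_params()) {
  g <- if (inherits(haplotypes, "ystar_sim")) haplotypes$genotypes else haplotypes
  stopifnot(is.matrix(g), !is.null(rownames(g)), !is.null(colnames(g)))
  with_seed(child_seed(params$seed, "reads"), {
    n <- length(g)
    depth <- rpois(n, params$depth_mean)
    p_alt <- ifelse(g == 1L, 1 - params$error_rate, params$error_rate)
    alt <- rbinom(n, depth, as.vector(p_alt))
    tibble::tibble(
      sample = rep(rownames(g), times = ncol(g)),
      site = rep(colnames(g), each = nrow(g)),
      ref_count = as.integer(depth - alt),
      alt_count = as.integer(alt)
    ) |> dplyr::arrange(.data$sample, .data$site)
  })
}

#' Write / read an allele-count matrix as TSV
#'
#' Wide TSV with one row per sample and one `ref,alt` cell per site, headed
#' by provenance comment lines. This is the interchange format between the
#' simulator and the calling stage, and the expected layout for user-supplied
#' count tables.
#'
#' @param counts Long tibble as returned by [simulate_reads()].
#' @param path File path.
#' @param params Optional named list recorded in the header.
#' @return `write_counts()` returns `path` invisibly; `read_counts()` returns
#'   the long tibble.
#' @export
write_counts <- function(counts, path, params = list()) {
  wide <- counts |>
    dplyr::mutate(cell = paste0(.data$ref_count, ",", .data$alt_count)) |>
    dplyr::select("sample", "site", "cell") |>
    tidyr::pivot_wider(names_from = "site", values_from = "cell")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header("allele counts (ref,alt per cell)", params), con)
  write.table(wide, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  wide <- read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                     check.names = FALSE, colClasses = "character")
  long <- tidyr::pivot_longer(tibble::as_tibble(wide), -"sample",
                              names_to = "site", values_to = "cell")
  parts <- strsplit(long$cell, ",", fixed = TRUE)
  long |>
    dplyr::mutate(
      ref_count = as.integer(vapply(parts, `[`, "", 1L)),
      alt_count = as.integer(vapply(parts, `[`, "", 2L))
    ) |>
    dplyr::select(-"cell")
}
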