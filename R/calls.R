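#' Site and sample quality policy for genotype-state calling
#'
#' Thresholds of the pooled-capture calling rules. Defaults are the panel's
#' published criteria: an alternative call needs at least 2 supporting reads
#' making up at least 3/4 of the cell's coverage (4 reads if the variant is
#' private to one sample), and a site enters tree building only when more
#' than 100 of the 110 cohort samples yield an unambiguous 0/1 call. For
#' cohorts of a different size the informative-call threshold scales
#' proportionally, recovering the published behaviour exactly at n = 110.
#'
#' @param min_informative Minimum unambiguous calls (strictly exceeded) out
#'   of `total_samples`.
#' @param total_samples Cohort size at which `min_informative` is quoted.
#' @param min_alt_reads Minimum alternative reads for a "1" call.
#' @param alt_fraction Minimum fraction of the cell's reads supporting the
#'   called allele (inclusive).
#' @param private_min_alt Minimum alternative reads for a "1" carried by a
#'   single sample (private SNP).
#' @return A `site_filter_policy` list.
#' @examples
#' site_filter_policy()
#' @export
site_filter_policy <- function(min_informative = 100, total_samples = 110,
                               min_alt_reads = 2, alt_fraction = 3 / 4,
                               private_min_alt = 4) {
  stopifnot(
    min_informative > 0, min_informative <= total_samples,
    min_alt_reads > 0, alt_fraction > 0, alt_fraction <= 1,
    private_min_alt > 0
  )
  structure(
    list(min_informative = min_informative, total_samples = total_samples,
         min_alt_reads = min_alt_reads, alt_fraction = alt_fraction,
         private_min_alt = private_min_alt),
    class = "site_filter_policy"
  )
}

#' Genotype state from one cell's read counts
#'
#' The four-state coding of a pooled-capture call: `"-"` no coverage, `"1"`
#' derived (alternative reads >= `min_alt_reads` and >= `alt_fraction` of the
#' cell total), `"0"` ancestral (reference reads >= `alt_fraction` of the
#' total), `"?"` ambiguous otherwise. Both fraction rules are inclusive at
#' exact ties. Vectorized over cells.
#'
#' @param ref_count,alt_count Non-negative integer read counts.
#' @param policy A [site_filter_policy()].
#' @return Character vector of states in `{"0","1","?","-"}`.
#' @examples
#' call_state(c(0, 5, 1, 0), c(2, 0, 2, 0))
#' @export
call_state <- function(ref_count, alt_count, policy = site_filter_policy()) {
  if (any(ref_count < 0) || any(alt_count < 0)) abort("negative read counts")
  total <- ref_count + alt_count
  dplyr::case_when(
    total == 0 ~ "-",
    alt_count >= policy$min_alt_reads &
      alt_count >= policy$alt_fraction * total ~ "1",
    ref_count >= policy$alt_fraction * total ~ "0",
    .default = "?"
  )
}

#' Call genotype states for a whole allele-count table
#'
#' @param counts Tibble with `sample`, `site`, `ref_count`, `alt_count`.
#' @param policy A [site_filter_policy()].
#' @return Tibble with `sample`, `site`, `state` — the call matrix in long
#'   form.
#' @examples
#' counts <- tibble::tibble(sample = "A", site = "F00001",
#'                          ref_count = 0L, alt_count = 3L)
#' call_genotypes(counts)
#' @export
call_genotypes <- function(counts, policy = site_filter_policy()) {
  stopifnot(all(c("sample", "site", "ref_count", "alt_count") %in% names(counts)))
  counts |>
    dplyr::mutate(state = call_state(.data$ref_count, .data$alt_count, policy)) |>
    dplyr::select("sample", "site", "state")
}

#' Demote under-covered private SNPs
#'
#' A variant observed in exactly one sample of the cohort (a private SNP) is
#' kept only when backed by at least `private_min_alt` alternative reads;
#' otherwise its lone "1" is demoted to "?". Sites with two or more carriers
#' are untouched.
#'
#' @param calls Long call tibble from [call_genotypes()].
#' @param counts The congruent allele-count tibble.
#' @param policy A [site_filter_policy()].
#' @return The call tibble with demotions applied.
#' @export
apply_private_filter <- function(calls, counts, policy = site_filter_policy()) {
  if (identical(calls$sample, counts$sample) &&
      identical(calls$site, counts$site)) {
    alt <- counts$alt_count
  } else {
    joined <- dplyr::left_join(calls, counts, by = c("sample", "site"))
    if (anyNA(joined$alt_count)) abort("calls and counts tables do not align")
    alt <- joined$alt_count
  }
  site_f <- factor(calls$site)
  is_one <- calls$state == "1"
  carriers <- tabulate(as.integer(site_f)[is_one], nbins = nlevels(site_f))
  demote <- is_one & carriers[as.integer(site_f)] == 1L &
    alt < policy$private_min_alt
  out <- calls
  out$state[demote] <- "?"
  dplyr::select(out, "sample", "site", "state")
}

#' Cohort coverage filter on sites
#'
#' Keeps sites whose number of unambiguous (0/1) calls strictly exceeds
#' `min_informative * n_samples / total_samples` — the published
#' "more than 100 out of 110" rule, scaled proportionally for other cohort
#' sizes. Optionally drops sites monomorphic among the retained samples,
#' which carry no signal for tree building.
#'
#' @param calls Long call tibble.
#' @param policy A [site_filter_policy()].
#' @param drop_monomorphic Drop sites whose unambiguous calls are all "0" or
#'   all "1"?
#' @return The filtered call tibble.
#' @export
filter_sites <- function(calls, policy = site_filter_policy(),
                         drop_monomorphic = TRUE) {
  n_samples <- dplyr::n_distinct(calls$sample)
  threshold <- policy$min_informative * n_samples / policy$total_samples
  site_f <- factor(calls$site)
  si <- as.integer(site_f)
  nb <- nlevels(site_f)
  n0 <- tabulate(si[calls$state == "0"], nbins = nb)
  n1 <- tabulate(si[calls$state == "1"], nbins = nb)
  keep <- (n0 + n1) > threshold
  if (drop_monomorphic) keep <- keep & n0 > 0 & n1 > 0
  calls[keep[si], , drop = FALSE]
}

#' Fold manual-curation states into analyzable calls
#'
#' Curated call tables may carry two post-hoc correction marks: `"x"`
#' (tested 1 but resolved to 0) and `"@"` (tested ? but resolved to 1).
#' These arise only from manual review against the phylogeny and are never
#' produced by automatic calling; for analysis they are folded to "0" and
#' "1" respectively.
#'
#' @param calls Long call tibble possibly containing `"x"` / `"@"` states.
#' @return The tibble with curation marks resolved.
#' @export
normalize_curation_states <- function(calls) {
  dplyr::mutate(calls, state = dplyr::recode(.data$state, x = "0", `@` = "1"))
}

#' Per-sample sequence quality tier
#'
#' Samples are tiered by mean targeted coverage: `"good"` above 6x (the only
#' tier admitted to time estimation by default), `"moderate"` between 1x and
#' 6x (admitted to tree building), `"low"` below 1x.
#'
#' @param mean_depth Numeric vector of per-sample mean depths.
#' @return Character vector of tiers.
#' @examples
#' quality_tier(c(6.5, 1.4, 0))
#' @export
quality_tier <- function(mean_depth) {
  dplyr::case_when(
    mean_depth > 6 ~ "good",
    mean_depth >= 1 ~ "moderate",
    .default = "low"
  )
}

#' Summarise per-sample coverage and tier
#'
#' @param counts Allele-count tibble.
#' @return Tibble with `sample`, `mean_depth`, `tier`.
#' @export
sample_quality <- function(counts) {
  counts |>
    dplyr::group_by(.data$sample) |>
    dplyr::summarise(mean_depth = mean(.data$ref_count + .data$alt_count)) |>
    dplyr::mutate(tier = quality_tier(.data$mean_depth))
}

#' Long call tibble to character matrix
#'
#' @param calls Long call tibble.
#' @return Character matrix samples x sites (sites in ID order).
#' @export
calls_matrix <- function(calls) {
  s <- factor(calls$sample)
  t <- factor(calls$site)
  m <- matrix(NA_character_, nlevels(s), nlevels(t),
              dimnames = list(levels(s), levels(t)))
  m[cbind(as.integer(s), as.integer(t))] <- calls$state
  if (anyNA(m)) abort("call table is not a complete sample x site grid")
  m
}

#' Character matrix back to long call tibble
#'
#' @param m Character matrix samples x sites.
#' @return Long call tibble.
#' @export
calls_from_matrix <- function(m) {
  tibble::tibble(
    sample = rep(rownames(m), times = ncol(m)),
    site = rep(colnames(m), each = nrow(m)),
    state = as.vector(m)
  )
}

#' Write / read a call matrix as TSV
#'
#' One character per cell from `{0,1,?,-,x,@}`, samples in rows, headed by
#' provenance comments.
#'
#' @param calls Long call tibble.
#' @param path File path.
#' @param params Optional named list recorded in the header.
#' @export
write_call_matrix <- function(calls, path, params = list()) {
  m <- calls_matrix(calls)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header("call matrix (states 0/1/?/-/x/@)", params), con)
  df <- data.frame(sample = rownames(m), m, check.names = FALSE)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_call_matrix
#' @export
read_call_matrix <- function(path) {
  wide <- read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                     check.names = FALSE, colClasses = "character")
  m <- as.matrix(wide[, -1L, drop = FALSE])
  rownames(m) <- wide$sample
  calls_from_matrix(m)
}

#' Write pseudo-sequences as FASTA
#'
#' Concatenates each sample's alleles at the retained variant sites into one
#' binary-allele pseudo-sequence (default encoding: ancestral "0" = A,
#' derived "1" = G), the substrate for parsimony tree building.
#'
#' @param calls Complete (imputed) long call tibble.
#' @param path File path.
#' @param alleles Named character vector mapping `"0"` and `"1"` to bases.
#' @export
write_pseudo_fasta <- function(calls, path, alleles = c(`0` = "A", `1` = "G")) {
  m <- calls_matrix(normalize_curation_states(calls))
  if (!all(m %in% c("0", "1"))) {
    abort("pseudo-sequences need a complete 0/1 matrix; impute first")
  }
  seqs <- apply(m, 1L, function(row) paste(alleles[row], collapse = ""))
  writeLines(as.vector(rbind(paste0(">", names(seqs)), seqs)), path)
  invisible(path)
}
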