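#' Capture-bait design parameters
#'
#' Tiling-uniqueness screening: `window`-bp fragments of the target are
#' generated every `step` bp, each is searched against the whole genome
#' allowing up to `max_mismatches` substitutions on either strand, only
#' fragments occurring exactly once are kept, their ranges are merged, and
#' merged ranges shorter than `min_merged_length` are discarded. Defaults
#' are the published design: 70-bp tiles every 10 bp, 0–2 mismatches,
#' 240-bp minimum.
#'
#' @param window Fragment length in bp.
#' @param step Tiling step in bp (0 < step <= window).
#' @param max_mismatches Maximum Hamming mismatches still counted as a
#'   match.
#' @param min_merged_length Minimum merged-range length retained.
#' @return A `bait_params` list.
#' @examples
#' bait_params()
#' @export
bait_params <- function(window = 70, step = 10, max_mismatches = 2,
                        min_merged_length = 240) {
  stopifnot(step > 0, step <= window, max_mismatches >= 0,
            min_merged_length >= window)
  structure(
    list(window = window, step = step, max_mismatches = max_mismatches,
         min_merged_length = min_merged_length),
    class = "bait_params"
  )
}

as_dna_set <- function(genome) {
  if (inherits(genome, "DNAStringSet")) return(genome)
  if (inherits(genome, "DNAString")) {
    g <- Biostrings::DNAStringSet(genome)
    names(g) <- "seq"
    return(g)
  }
  stopifnot(is.character(genome))
  if (is.null(names(genome))) names(genome) <- paste0("seq", seq_along(genome))
  Biostrings::DNAStringSet(toupper(genome))
}

#' Tile a target sequence into overlapping fragments
#'
#' Fragments start at offsets `0, step, 2*step, ...` with the last offset at
#' most `length - window`; with a 100-bp target and default parameters that
#' is offsets 0, 10, 20, 30. Both 0-based offsets and the equivalent
#' 1-based inclusive coordinates are reported (tile one of a chromosome is
#' `1-70`, tile two `11-80`).
#'
#' @param target Target sequence (character scalar or `DNAString`).
#' @param params A [bait_params()].
#' @return Tibble with `offset` (0-based), `start1`, `end1` (1-based
#'   inclusive), `fragment`.
#' @examples
#' tile_fragments(paste(rep("ACGT", 25), collapse = ""))
#' @export
tile_fragments <- function(target, params = bait_params()) {
  s <- if (inherits(target, "DNAString")) as.character(target) else toupper(target)
  len <- nchar(s)
  if (len < params$window) abort("target shorter than the fragment window")
  offs <- seq(0L, len - params$window, by = params$step)
  tibble::tibble(
    offset = as.integer(offs),
    start1 = as.integer(offs + 1L),
    end1 = as.integer(offs + params$window),
    fragment = substring(s, offs + 1L, offs + params$window)
  )
}

# Mask ambiguity: an N must match nothing, including another N. Encoding
# query Ns as "+" and subject Ns as "-" keeps them in the DNA alphabet while
# guaranteeing a mismatch at every alignment (reverse-complement maps "+"
# and "-" to themselves).
mask_query <- function(x) chartr("N", "+", x)
mask_subject_set <- function(set) {
  Biostrings::DNAStringSet(chartr("N", "-", as.character(set)))
}

#' Count genome-wide occurrences of a fragment
#'
#' Number of positions in the genome (both strands unless
#' `both_strands = FALSE`) where the fragment aligns with Hamming distance
#' at most `max_mismatches`. `N` in either sequence matches nothing.
#'
#' @param fragment Character scalar over `A,C,G,T,N`.
#' @param genome Named character vector, `DNAString`, or `DNAStringSet`.
#' @param max_mismatches Maximum mismatches.
#' @param both_strands Also count reverse-complement alignments?
#' @return Integer occurrence count.
#' @examples
#' count_matches("ACGTACGTAC", c(chr1 = "TTTTACGTACGTACTTTT"), 0)
#' @export
count_matches <- function(fragment, genome, max_mismatches = 2,
                          both_strands = TRUE) {
  stopifnot(is.character(fragment), length(fragment) == 1L)
  subj <- mask_subject_set(as_dna_set(genome))
  pat <- Biostrings::DNAString(mask_query(toupper(fragment)))
  n <- sum(Biostrings::vcountPattern(pat, subj,
                                     max.mismatch = max_mismatches,
                                     fixed = TRUE))
  if (both_strands) {
    rc <- Biostrings::reverseComplement(pat)
    n <- n + sum(Biostrings::vcountPattern(rc, subj,
                                           max.mismatch = max_mismatches,
                                           fixed = TRUE))
  }
  as.integer(n)
}

#' Unique-tile capture regions of a target
#'
#' Runs the full tiling-uniqueness screen: every tile of `target` (which
#' must be one of the genome's sequences) is counted against the whole
#' genome; tiles occurring anywhere beyond their own origin — on either
#' strand, within `max_mismatches` — are discarded; the surviving tiles'
#' ranges are merged (overlapping or abutting runs combine) and merged
#' ranges shorter than `min_merged_length` are dropped.
#'
#' @param target Name of the target sequence within `genome`.
#' @param genome Named character vector or `DNAStringSet` containing the
#'   target and all off-target sequences.
#' @param params A [bait_params()].
#' @param both_strands Count reverse-complement matches as repeats?
#' @return A `bait_regions` tibble with `start`, `end` (0-based half-open)
#'   and `start1`, `end1`, `width`; attributes `target`, `params`,
#'   `covered_bp`, `n_tiles`, `n_unique_tiles`.
#' @examples
#' set.seed(1)
#' g <- paste(sample(c("A","C","G","T"), 500, TRUE), collapse = "")
#' unique_regions("chrY", c(chrY = g), bait_params(min_merged_length = 70))
#' @export
unique_regions <- function(target, genome, params = bait_params(),
                           both_strands = TRUE) {
  gset <- as_dna_set(genome)
  if (!target %in% names(gset)) abort("target sequence not found in genome")
  tseq <- as.character(gset[[target]])
  tiles <- tile_fragments(tseq, params)
  subj <- mask_subject_set(gset)
  occ <- vapply(tiles$fragment, function(fr) {
    pat <- Biostrings::DNAString(mask_query(fr))
    n <- sum(Biostrings::vcountPattern(pat, subj,
                                       max.mismatch = params$max_mismatches,
                                       fixed = TRUE))
    if (both_strands) {
      rc <- Biostrings::reverseComplement(pat)
      n <- n + sum(Biostrings::vcountPattern(rc, subj,
                                             max.mismatch = params$max_mismatches,
                                             fixed = TRUE))
    }
    as.integer(n)
  }, 0L, USE.NAMES = FALSE)
  # a tile's own forward origin is always one of its hits (unless it
  # contains N, which matches nothing and can never be unique)
  has_n <- grepl("N", tiles$fragment, fixed = TRUE)
  uniq <- !has_n & occ == 1L
  ir <- IRanges::reduce(IRanges::IRanges(
    start = tiles$start1[uniq], end = tiles$end1[uniq]
  ))
  ir <- ir[IRanges::width(ir) >= params$min_merged_length]
  out <- tibble::tibble(
    start = as.integer(IRanges::start(ir) - 1L),
    end = as.integer(IRanges::end(ir)),
    start1 = as.integer(IRanges::start(ir)),
    end1 = as.integer(IRanges::end(ir)),
    width = as.integer(IRanges::width(ir))
  )
  structure(out, class = c("bait_regions", class(out)),
            target = target, params = params,
            covered_bp = sum(out$width), n_tiles = nrow(tiles),
            n_unique_tiles = sum(uniq))
}

#' Write bait regions as BED and 1-based TSV
#'
#' `write_bed()` emits 0-based half-open BED; `write_regions_tsv()` emits
#' the 1-based inclusive companion table matching the supplementary-table
#' convention. Output is byte-deterministic for identical inputs.
#'
#' @param regions A `bait_regions` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  lines <- sprintf("%s\t%d\t%d", attr(regions, "target"),
                   regions$start, regions$end)
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_bed
#' @export
write_regions_tsv <- function(regions, path) {
  con <- file(path, "w")
  on.exit(close(con))
  p <- attr(regions, "params")
  writeLines(provenance_header("bait regions (1-based inclusive)", list(
    target = attr(regions, "target"), window = p$window, step = p$step,
    max_mismatches = p$max_mismatches, min_merged_length = p$min_merged_length
  )), con)
  writeLines("chrom\tstart\tend\twidth", con)
  writeLines(sprintf("%s\t%d\t%d\t%d", attr(regions, "target"),
                     regions$start1, regions$end1, regions$width), con)
  invisible(path)
}
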