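# Independent brute-force oracles and shared fixture builders. Everything
# here is deliberately naive and separate from the package implementation.

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

revcomp_chr <- function(x) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

# Naive Hamming occurrence count: slide the fragment over every sequence and
# strand, counting alignments with <= max_mm mismatches. N (either side)
# mismatches everything, including N.
oracle_count_matches <- function(fragment, genome, max_mm, both_strands = TRUE) {
  count_one <- function(frag, seq) {
    f <- utf8ToInt(chartr("N", "!", frag))
    s <- utf8ToInt(chartr("N", "#", seq))
    w <- length(f)
    n_off <- length(s) - w + 1L
    if (n_off < 1L) return(0L)
    mm <- integer(n_off)
    for (j in seq_len(w)) {
      mm <- mm + (s[j:(j + n_off - 1L)] != f[j])
    }
    sum(mm <= max_mm)
  }
  total <- 0L
  for (seq in genome) {
    total <- total + count_one(fragment, seq)
    if (both_strands) total <- total + count_one(revcomp_chr(fragment), seq)
  }
  total
}

# Naive tiling-uniqueness screen mirroring the published procedure.
oracle_unique_regions <- function(target, genome, window = 70, step = 10,
                                  max_mm = 2, min_len = 240,
                                  both_strands = TRUE) {
  tseq <- genome[[target]]
  offs <- seq(0L, nchar(tseq) - window, by = step)
  frags <- substring(tseq, offs + 1L, offs + window)
  uniq <- vapply(seq_along(frags), function(i) {
    !grepl("N", frags[i], fixed = TRUE) &&
      oracle_count_matches(frags[i], genome, max_mm, both_strands) == 1L
  }, TRUE)
  iv <- cbind(start = offs[uniq], end = offs[uniq] + window)  # 0-based half-open
  if (!nrow(iv)) {
    return(data.frame(start = integer(), end = integer()))
  }
  iv <- iv[order(iv[, 1L]), , drop = FALSE]
  merged <- list(iv[1L, ])
  for (i in seq_len(nrow(iv))[-1L]) {
    last <- merged[[length(merged)]]
    if (iv[i, "start"] <= last["end"]) {
      last["end"] <- max(last["end"], iv[i, "end"])
      merged[[length(merged)]] <- last
    } else {
      merged[[length(merged) + 1L]] <- iv[i, ]
    }
  }
  out <- do.call(rbind, merged)
  out <- out[out[, "end"] - out[, "start"] >= min_len, , drop = FALSE]
  data.frame(start = as.integer(out[, "start"]), end = as.integer(out[, "end"]))
}

# A genome whose off-target sequence carries a copy of the 1 kb target with
# a fully divergent central segment [div_start, div_start + div_len), so
# only tiles overlapping the divergent segment by more than max_mm bases
# are unique.
island_genome <- function(div_start = 100, div_len = 105, target_len = 1000) {
  tgt <- rand_dna(target_len)
  copy <- paste0(
    substring(tgt, 1, div_start),
    chartr("ACGT", "CGTA", substring(tgt, div_start + 1, div_start + div_len)),
    substring(tgt, div_start + div_len + 1, target_len)
  )
  c(chrY = tgt, decoy = copy)
}

# genome with a planted duplication of a target block (possibly mutated at
# `n_mm` positions) on an off-target sequence
dup_genome <- function(target_len = 800, block = c(301, 500), n_mm = 0) {
  tgt <- rand_dna(target_len)
  dup <- substring(tgt, block[1], block[2])
  if (n_mm > 0) {
    pos <- sample(nchar(dup), n_mm)
    chars <- strsplit(dup, "")[[1]]
    chars[pos] <- vapply(chars[pos], function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1L)
    }, "")
    dup <- paste(chars, collapse = "")
  }
  other <- rand_dna(target_len)
  c(chrY = tgt,
    decoy = paste0(substring(other, 1, 300), dup, substring(other, 301, target_len)))
}

# Non-trivial clades (tip label sets) of a tree, optionally only those whose
# subtending branch carries a positive substitution count.
splits_of <- function(phy, positive_only = FALSE) {
  n_tip <- length(phy$tip.label)
  out <- character(0)
  for (i in seq_len(nrow(phy$edge))) {
    v <- phy$edge[i, 2L]
    if (v <= n_tip) next
    if (positive_only && phy$edge.length[i] == 0) next
    tips <- sort(phy$tip.label[unlist(tips_under_node(phy, v))])
    out <- c(out, paste(tips, collapse = "|"))
  }
  sort(out)
}

tips_under_node <- function(phy, node) {
  n_tip <- length(phy$tip.label)
  if (node <= n_tip) return(node)
  kids <- phy$edge[phy$edge[, 1L] == node, 2L]
  unlist(lapply(kids, tips_under_node, phy = phy))
}

# genotype matrix of a simulation as a character call matrix
sim_call_matrix <- function(sim) {
  m <- matrix(as.character(sim$genotypes), nrow(sim$genotypes),
              dimnames = dimnames(sim$genotypes))
  m
}

# strip bait_regions down to the bare interval table for oracle comparison
regions_df <- function(ur) data.frame(start = ur$start, end = ur$end)
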