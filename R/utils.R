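# Shared internal helpers: interval arithmetic, sequence access, validation.
# All interval columns package-wide are 1-based inclusive ([start, end]),
# the GRanges/GFF convention; BED/BedGraph files are converted at the I/O
# boundary.

DNA_BASES <- c("A", "C", "G", "T")

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' All 12 ordered single-nucleotide substitution types
#'
#' Reference-to-alternate pairs on the plus strand, e.g. `"G>A"`.
#'
#' @return Character vector of length 12.
#' @export
mutation_types <- function() {
  out <- character(0)
  for (r in DNA_BASES) for (a in setdiff(DNA_BASES, r)) {
    out <- c(out, paste0(r, ">", a))
  }
  out
}

# Extract genome base(s): `genome` is an ems_genome, `chrom`/`pos` vectors.
genome_base <- function(genome, chrom, pos) {
  out <- character(length(pos))
  for (ch in unique(chrom)) {
    i <- chrom == ch
    out[i] <- vapply(
      pos[i],
      function(p) substr(genome$seq[[ch]], p, p),
      character(1)
    )
  }
  out
}

# Faster variant for many positions on one chromosome.
genome_bases_chr <- function(seq_string, pos) {
  substring(seq_string, pos, pos)
}

#' Chromosome lengths of a simulated genome
#'
#' @param genome An `ems_genome` object (see [sim_genome()]).
#' @return Named numeric vector of chromosome lengths in bp.
#' @export
chrom_lengths <- function(genome) {
  vapply(genome$seq, nchar, numeric(1))
}

# Merge 1-based inclusive intervals, joining pairs whose gap (bases strictly
# between them) is <= gap. gap = 0 merges overlapping/adjacent only.
merge_intervals <- function(df, gap = 0) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  if (nrow(df) == 0) return(df[, c("chrom", "start", "end")])
  if (any(df$start < 1) || any(df$end < df$start)) {
    abort("intervals must satisfy 1 <= start <= end")
  }
  df <- dplyr::arrange(df, .data$chrom, .data$start, .data$end)
  out <- dplyr::group_modify(
    dplyr::group_by(df, .data$chrom),
    function(d, key) {
      s <- d$start
      e <- d$end
      keep_s <- s[1]
      keep_e <- e[1]
      res_s <- numeric(0)
      res_e <- numeric(0)
      if (nrow(d) > 1) {
        for (i in 2:nrow(d)) {
          if (s[i] - keep_e - 1 <= gap) {
            keep_e <- max(keep_e, e[i])
          } else {
            res_s <- c(res_s, keep_s)
            res_e <- c(res_e, keep_e)
            keep_s <- s[i]
            keep_e <- e[i]
          }
        }
      }
      tibble(start = c(res_s, keep_s), end = c(res_e, keep_e))
    }
  )
  dplyr::ungroup(out)
}

# Midpoint (integer, floor of the centre) of 1-based inclusive intervals.
interval_midpoint <- function(start, end) {
  floor((start + end) / 2)
}

reverse_complement <- function(x) {
  vapply(x, function(s) {
    paste(rev(COMPLEMENT[strsplit(s, "", fixed = TRUE)[[1]]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Deterministic sub-seed derivation (kept well below 2^31).
derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(offset)
}

check_fraction <- function(x, name) {
  if (!is.numeric(x) || any(x < 0) || any(x > 1)) {
    abort(paste0("`", name, "` must be within [0, 1]"))
  }
  invisible(x)
}
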