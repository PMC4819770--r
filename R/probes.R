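#' Scan a transcript for candidate FISH oligos
#'
#' Slides a window of `oligo_len` (default 50 nt) along the target and
#' keeps every window whose GC fraction lies within `gc_tol` of
#' `gc_target` — probes in a set should share roughly the same GC content
#' (~55%) so they hybridize with similar efficiency. Windows containing
#' ambiguous bases are skipped.
#'
#' @param target Target sequence: character string or
#'   [Biostrings::DNAString].
#' @param oligo_len Oligo length (default 50).
#' @param gc_target,gc_tol GC fraction target and tolerance
#'   (defaults 0.55 +/- 0.05).
#' @return Tibble of candidates: `start` (0-based offset on the target),
#'   `sequence`, `gc_fraction`.
#' @export
scan_candidates <- function(target, oligo_len = 50, gc_target = 0.55,
                            gc_tol = 0.05) {
  seq <- toupper(as.character(target))
  L <- nchar(seq)
  if (L < oligo_len) {
    nanosep_abort("Target shorter than the oligo length.",
                  "nanosep_domain_error")
  }
  ch <- strsplit(seq, "")[[1]]
  is_gc <- as.integer(ch %in% c("G", "C"))
  is_acgt <- as.integer(ch %in% c("A", "C", "G", "T"))
  gc_run <- cumsum_window(is_gc, oligo_len)
  ok_run <- cumsum_window(is_acgt, oligo_len)
  gc_frac <- gc_run / oligo_len
  keep <- ok_run == oligo_len & abs(gc_frac - gc_target) <= gc_tol + 1e-12
  starts <- which(keep) - 1L
  if (length(starts) == 0) {
    return(tibble(start = integer(0), sequence = character(0),
                  gc_fraction = numeric(0)))
  }
  tibble(
    start = starts,
    sequence = substring(seq, starts + 1L, starts + oligo_len),
    gc_fraction = gc_frac[keep]
  )
}

cumsum_window <- function(x, w) {
  cs <- cumsum(x)
  cs[w:length(x)] - c(0, cs)[1:(length(x) - w + 1)]
}

#' Assign fluor-bearing modified bases within an oligo
#'
#' Fluors attached to bases only a few bases apart quench each other, so
#' modified (amino-dT) positions must be spaced more than ~8 bases apart —
#' implemented as pairwise gap >= `min_spacing` (default 9). Among the
#' oligo's T positions, `n_mods` are chosen to maximize the minimum
#' pairwise spacing (ties resolved leftmost, so the choice is
#' deterministic). Candidates where no such placement exists — too few T's
#' or T's too crowded — are flagged, not errored.
#'
#' @param candidates Candidate tibble from [scan_candidates()] (or any
#'   tibble with a `sequence` column).
#' @param n_mods Modified bases per oligo (default 5 for a 50-mer).
#' @param min_spacing Minimum allowed gap between modified positions
#'   (default 9, i.e. strictly more than 8 bases apart).
#' @return The tibble with `modified_T_positions` (list column of 0-based
#'   offsets), `min_mod_gap`, and `mod_flag` (`NA` when the placement is
#'   valid).
#' @export
assign_modified_bases <- function(candidates, n_mods = 5, min_spacing = 9) {
  cand <- as_tibble(candidates)
  res <- map(cand$sequence, function(s) {
    tpos <- which(strsplit(toupper(s), "")[[1]] == "T") - 1L
    if (length(tpos) < n_mods) {
      return(list(pos = list(tpos), gap = NA_real_, flag = "too_few_T"))
    }
    sel <- max_min_spacing_subset(tpos, n_mods)
    gap <- if (n_mods > 1) min(diff(sel)) else Inf
    flag <- if (gap < min_spacing) "mods_too_close" else NA_character_
    list(pos = list(sel), gap = gap, flag = flag)
  })
  cand$modified_T_positions <- map(res, ~ .x$pos[[1]])
  cand$min_mod_gap <- map_dbl(res, "gap")
  cand$mod_flag <- map_chr(res, "flag")
  cand
}

# choose m of the sorted positions maximizing the minimum pairwise gap;
# binary search on the gap + greedy feasibility, greedy-leftmost at the
# optimum (deterministic)
max_min_spacing_subset <- function(positions, m) {
  positions <- sort(positions)
  greedy <- function(gap) {
    sel <- positions[1]
    for (p in positions[-1]) {
      if (p - sel[length(sel)] >= gap) sel <- c(sel, p)
      if (length(sel) == m) break
    }
    sel
  }
  lo <- 0L; hi <- max(positions) - min(positions)
  while (lo < hi) {
    mid <- (lo + hi + 1L) %/% 2L
    if (length(greedy(mid)) >= m) lo <- mid else hi <- mid - 1L
  }
  greedy(lo)[seq_len(m)]
}

#' Screen an oligo for genomic uniqueness
#'
#' A probe must not contain any 20-nt segment that maps exactly elsewhere
#' in the genome (either strand): 20-mers are long enough to hybridize
#' uniquely in the human transcriptome, so a shared 20-mer is a potential
#' off-target site. The screen fails if any length-`k` substring of the
#' candidate occurs exactly in the background set or its reverse
#' complement.
#'
#' @param candidate Candidate sequence (character).
#' @param background Background sequences: [Biostrings::DNAStringSet],
#'   character vector, or path handled by [read_fasta()].
#' @param k Segment length (default 20; must not exceed the oligo length).
#' @return List with `passed` (logical) and `offending_kmers` (character).
#' @export
uniqueness_screen <- function(candidate, background, k = 20) {
  candidate <- toupper(as.character(candidate))
  if (k > nchar(candidate)) {
    nanosep_abort("`k` must not exceed the oligo length.",
                  "nanosep_domain_error")
  }
  bg <- as_dna_set(background)
  if (length(bg) == 0) return(list(passed = TRUE, offending_kmers = character(0)))
  bg_both <- c(bg, Biostrings::reverseComplement(bg))
  starts <- seq_len(nchar(candidate) - k + 1L)
  kmers <- unique(substring(candidate, starts, starts + k - 1L))
  hit <- map_lgl(kmers, function(km) {
    any(Biostrings::vcountPattern(km, bg_both) > 0)
  })
  list(passed = !any(hit), offending_kmers = kmers[hit])
}

as_dna_set <- function(x) {
  if (inherits(x, "DNAStringSet")) return(x)
  if (is.character(x) && length(x) == 1 && file.exists(x)) {
    return(Biostrings::readDNAStringSet(x))
  }
  Biostrings::DNAStringSet(toupper(x))
}

#' Read a FASTA file
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()].
#'
#' @param path FASTA path.
#' @return A `DNAStringSet`.
#' @export
read_fasta <- function(path) Biostrings::readDNAStringSet(path)

#' Assemble a probe set of minimal span
#'
#' Selects `set_size` non-overlapping candidates whose transcript span
#' (max end minus min start) is smallest; probe sets must lie within
#' `max_span` nucleotides (default 600, the contour-length bound for a
#' target to behave like a point source), ideally within `ideal_span`
#' (default 400, warned otherwise). For each possible leftmost candidate
#' the earliest-ending non-overlapping chain is taken, which is
#' span-optimal for that leftmost choice; the best chain over all leftmost
#' choices is returned, ties broken by leftmost start.
#'
#' @param candidates Candidate tibble (columns `start`, `sequence`; rows
#'   flagged by [assign_modified_bases()] or failing
#'   [uniqueness_screen()] should be filtered out beforehand).
#' @param set_size Probes per set (default 5).
#' @param max_span Hard span limit in nt (default 600).
#' @param ideal_span Soft span limit in nt (default 400).
#' @return A `probe_set`: list with `probes` (tibble), `span_nt`,
#'   `within_ideal`.
#' @export
assemble_probe_set <- function(candidates, set_size = 5, max_span = 600,
                               ideal_span = 400) {
  cand <- arrange(as_tibble(candidates), .data$start)
  if (nrow(cand) < set_size) {
    nanosep_abort(sprintf(
      "Infeasible: %d passing candidates, need %d.", nrow(cand), set_size),
      "nanosep_infeasible")
  }
  len <- nchar(cand$sequence)
  ends <- cand$start + len   # exclusive
  best <- NULL
  for (i in seq_len(nrow(cand))) {
    sel <- i
    repeat {
      if (length(sel) == set_size) break
      nxt <- which(cand$start >= ends[sel[length(sel)]])
      nxt <- nxt[nxt > sel[length(sel)]]
      if (length(nxt) == 0) break
      # earliest-ending continuation minimizes the final end
      j <- nxt[which.min(ends[nxt])]
      sel <- c(sel, j)
    }
    if (length(sel) < set_size) next
    span <- max(ends[sel]) - min(cand$start[sel])
    if (is.null(best) || span < best$span) best <- list(sel = sel, span = span)
  }
  if (is.null(best)) {
    nanosep_abort("Infeasible: no non-overlapping set of the requested size.",
                  "nanosep_infeasible")
  }
  if (best$span > max_span) {
    nanosep_abort(sprintf(
      "Infeasible: best achievable span %d nt exceeds the %d-nt limit.",
      best$span, max_span), "nanosep_infeasible")
  }
  if (best$span > ideal_span) {
    warn(sprintf("Probe-set span %d nt exceeds the ideal %d nt.",
                 best$span, ideal_span))
  }
  structure(
    list(probes = cand[best$sel, ], span_nt = best$span,
         within_ideal = best$span <= ideal_span),
    class = "probe_set")
}

#' @export
print.probe_set <- function(x, ...) {
  cat(sprintf("<probe_set> %d probes, span %d nt%s\n", nrow(x$probes),
              x$span_nt, if (x$within_ideal) "" else " (above ideal span)"))
  invisible(x)
}

#' @export
tidy.probe_set <- function(x, ...) x$probes

#' @export
glance.probe_set <- function(x, ...) {
  tibble(n_probes = nrow(x$probes), span_nt = x$span_nt,
         within_ideal = x$within_ideal)
}

#' Full probe-design screen
#'
#' Convenience pipeline: scan the target for GC-matched windows, assign
#' modified bases, screen against the background for shared 20-mers, and
#' assemble the minimal-span set from the passing candidates.
#'
#' @inheritParams scan_candidates
#' @inheritParams assign_modified_bases
#' @inheritParams assemble_probe_set
#' @param background Optional background sequences for the uniqueness
#'   screen.
#' @param k Uniqueness segment length (default 20).
#' @return List with `candidates` (annotated tibble) and `probe_set`
#'   (or `NULL` with a warning when infeasible).
#' @export
design_probes <- function(target, background = NULL, oligo_len = 50,
                          gc_target = 0.55, gc_tol = 0.05, n_mods = 5,
                          min_spacing = 9, k = 20, set_size = 5,
                          max_span = 600, ideal_span = 400) {
  cand <- scan_candidates(target, oligo_len, gc_target, gc_tol)
  cand <- assign_modified_bases(cand, n_mods, min_spacing)
  if (!is.null(background) && nrow(cand) > 0) {
    bg <- as_dna_set(background)
    screens <- map(cand$sequence, uniqueness_screen, background = bg, k = k)
    cand$unique_ok <- map_lgl(screens, "passed")
    cand$offending_kmers <- map(screens, "offending_kmers")
  } else {
    cand$unique_ok <- TRUE
    cand$offending_kmers <- list(character(0))
  }
  passing <- filter(cand, is.na(.data$mod_flag), .data$unique_ok)
  set <- tryCatch(
    assemble_probe_set(passing, set_size, max_span, ideal_span),
    nanosep_infeasible = function(e) {
      warn(conditionMessage(e))
      NULL
    })
  list(candidates = cand, probe_set = set)
}
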