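#' Sliding-window uracil-content profile
#'
#' Computes, for every window start, the fraction of T/U bases in a fixed-size
#' window. This is the classic composition profile used to visualise U-rich
#' stretches in transcripts; the 55-nt default window matches the resolution
#' at which ~60-nt U-rich, transmembrane-helix-encoding segments stand out.
#'
#' Windows are 0-based and half-open: the window at position `p` covers
#' `sequence[p, p + window)`.
#'
#' @param sequence nucleotide string (A/C/G/T/U, case-insensitive).
#' @param window window size in nt (must not exceed the sequence length).
#' @param step offset between consecutive window starts.
#' @return A data frame of class `u_profile` with columns `position` (0-based
#'   window start) and `u_fraction`, plus `window`/`step` attributes.
#' @examples
#' u_content_profile("ACGTACGTACGT", window = 4, step = 4)$u_fraction
#' @export
u_content_profile <- function(sequence, window = 55L, step = 1L) {
  x <- seq_chars(sequence)
  window <- as.integer(window)
  step <- as.integer(step)
  if (window < 1 || step < 1) stop("window and step must be >= 1", call. = FALSE)
  if (length(x) < window) {
    stop("sequence (", length(x), " nt) shorter than window (", window, " nt)",
         call. = FALSE)
  }
  is_u <- as.integer(x %in% c("T", "U"))
  cs <- c(0L, cumsum(is_u))
  starts <- seq.int(0L, length(x) - window, by = step)
  out <- data.frame(
    position = starts,
    u_fraction = (cs[starts + window + 1L] - cs[starts + 1L]) / window)
  attr(out, "window") <- window
  attr(out, "step") <- step
  class(out) <- c("u_profile", "data.frame")
  out
}

# Split a sequence into an uppercase character vector, T/U preserved,
# rejecting anything outside the A/C/G/T/U alphabet.
seq_chars <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  x <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(x), c("A", "C", "G", "T", "U"))
  if (length(bad) > 0) {
    stop("sequence contains non-A/C/G/T/U characters: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  x
}

STOP_CODONS <- c("TAA", "TAG", "TGA")
SD_CANONICAL <- "AGGAGG"

# All maximal intervals (1-based, inclusive) matching >= 4 consecutive bases
# of the canonical Shine-Dalgarno hexamer AGGAGG.
find_sd_motifs <- function(x) {
  n <- length(x)
  kmers <- unique(vapply(1:3, function(i) substr(SD_CANONICAL, i, i + 3),
                         character(1)))
  hit <- logical(n)  # hit[p]: a matching 4-mer starts at p
  if (n >= 4) {
    quads <- paste0(x[1:(n - 3)], x[2:(n - 2)], x[3:(n - 1)], x[4:n])
    hit[seq_along(quads)] <- quads %in% kmers
  }
  starts <- which(hit)
  if (length(starts) == 0) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  # merge overlapping 4-mer hits into maximal motif intervals
  iv_start <- integer(0); iv_end <- integer(0)
  cur_s <- starts[1]; cur_e <- starts[1] + 3L
  for (p in starts[-1]) {
    if (p <= cur_e) {
      cur_e <- max(cur_e, p + 3L)
    } else {
      iv_start <- c(iv_start, cur_s); iv_end <- c(iv_end, cur_e)
      cur_s <- p; cur_e <- p + 3L
    }
  }
  iv_start <- c(iv_start, cur_s); iv_end <- c(iv_end, cur_e)
  data.frame(start = iv_start, end = iv_end)
}

# 1-based start positions of codon `triplet` matches in frame `frame` (0-based)
frame_codon_positions <- function(x, frame, triplets) {
  n <- length(x)
  starts <- seq.int(frame + 1L, n - 2L, by = 3L)
  if (length(starts) == 0) return(integer(0))
  codons <- paste0(x[starts], x[starts + 1L], x[starts + 2L])
  starts[codons %in% triplets]
}

#' Check a sequence for translatability signals
#'
#' Pure scan reporting start codons and stop codons per reading frame and
#' Shine-Dalgarno-like motifs (any >= 4-base match to AGGAGG). Motifs whose 3'
#' end lies 4-14 nt upstream of a start codon are flagged separately, since
#' that spacing is what makes a motif a plausible ribosome binding site.
#'
#' @param sequence nucleotide string.
#' @param frames 0-based reading frames to scan (subset of 0, 1, 2).
#' @param start_codons start-codon set; `ATG` by default, add `GTG`/`TTG`
#'   for the extended bacterial set.
#' @return A list of class `translatability_report`: `start_codons` and
#'   `stop_codons` (named integer vectors, one entry per scanned frame, named
#'   `frame0` ...), `start_positions`, `sd_motifs` (data frame of motif
#'   `start`/`end`, 1-based inclusive), and `sd_near_start` (motifs 4-14 nt
#'   upstream of a start codon in any scanned frame).
#' @examples
#' verify_untranslatable("AGGAGGAAAAATG")$sd_near_start
#' @export
verify_untranslatable <- function(sequence, frames = c(0, 1, 2),
                                  start_codons = "ATG") {
  x <- seq_chars(sequence)
  x[x == "U"] <- "T"
  frames <- sort(unique(as.integer(frames)))
  stopifnot(all(frames %in% 0:2))

  starts <- lapply(frames, function(f) frame_codon_positions(x, f, start_codons))
  stops <- lapply(frames, function(f) frame_codon_positions(x, f, STOP_CODONS))
  fr_names <- paste0("frame", frames)
  motifs <- find_sd_motifs(x)

  # a motif is "near" a start if any of its matching 4-mers ends 4-14 nt
  # upstream of a start codon (the merged interval may extend past the
  # spacing-relevant match, so spacing is judged per 4-mer)
  all_start_pos <- sort(unlist(starts))
  near <- motifs[rep(FALSE, nrow(motifs)), , drop = FALSE]
  if (nrow(motifs) > 0 && length(all_start_pos) > 0) {
    kmers <- unique(vapply(1:3, function(i) substr(SD_CANONICAL, i, i + 3),
                           character(1)))
    hits <- which(vapply(seq_len(max(length(x) - 3L, 0L)), function(i) {
      paste(x[i:(i + 3L)], collapse = "") %in% kmers
    }, logical(1)))
    good_hits <- hits[vapply(hits, function(h) {
      any(all_start_pos - h - 4L >= 4 & all_start_pos - h - 4L <= 14)
    }, logical(1))]
    keep <- vapply(seq_len(nrow(motifs)), function(i) {
      any(good_hits >= motifs$start[i] & good_hits <= motifs$end[i] - 3L)
    }, logical(1))
    near <- motifs[keep, , drop = FALSE]
  }

  structure(list(
    start_codons = stats::setNames(lengths(starts), fr_names),
    stop_codons = stats::setNames(lengths(stops), fr_names),
    start_positions = stats::setNames(starts, fr_names),
    sd_motifs = motifs,
    sd_near_start = near),
    class = "translatability_report")
}

#' @export
print.translatability_report <- function(x, ...) {
  cat("Translatability report\n")
  cat("  start codons:", paste(names(x$start_codons), x$start_codons,
                               sep = "=", collapse = " "), "\n")
  cat("  stop codons: ", paste(names(x$stop_codons), x$stop_codons,
                               sep = "=", collapse = " "), "\n")
  cat("  SD-like motifs:", nrow(x$sd_motifs),
      "(", nrow(x$sd_near_start), "within 4-14 nt of a start )\n")
  invisible(x)
}

#' Design an untranslatable mimic of an ORF segment
#'
#' Rewrites a sense-strand ORF segment into a transcript that preserves the
#' nucleotide composition (in particular its windowed U-content profile) while
#' being untranslatable: every start codon in the scanned frames is destroyed
#' by a single-base substitution, a TAA stop codon is written in frame 0 every
#' `stop_period_codons` codons, and Shine-Dalgarno-like motifs are disrupted.
#' Such mimics allow protein-RNA interaction studies decoupled from
#' translation.
#'
#' Substitutions are deterministic: among the single-base changes that destroy
#' the target without creating a new start codon, damaging a frame-0 stop, or
#' leaving an SD-like motif, the one that keeps the mimic's running T count
#' closest to the source's is taken, with ties broken by position and then by
#' the fixed base order T, A, C, G. This keeps the windowed U-content profile
#' of the mimic aligned with its source even after TAA stops are written; a
#' residual drift above 2 T per 100 nt triggers a warning.
#'
#' @param orf_segment nucleotide string, length divisible by 3.
#' @param stop_period_codons period of the frame-0 stop decoration; stops are
#'   written at 0-based codon indices `stop_period_codons - 1`,
#'   `2 * stop_period_codons - 1`, ...
#' @param frames_scanned 0-based frames in which start codons are removed.
#' @param start_codons start-codon set to destroy (default ATG only).
#' @return A list of class `mimic_design`: `source_sequence`,
#'   `mimic_sequence`, `edits` (data frame of 1-based `position`, `old`,
#'   `new`, `reason` in `start_removal`/`stop_insertion`/`sd_disruption`),
#'   and `report`, the [verify_untranslatable()] result for the mimic plus
#'   `n_stop_events` and source/mimic T counts.
#' @examples
#' d <- design_untranslatable_mimic(simulate_orf(20, seed = 1))
#' d$report$start_codons[["frame0"]]
#' @export
design_untranslatable_mimic <- function(orf_segment, stop_period_codons = 15L,
                                        frames_scanned = c(0, 1, 2),
                                        start_codons = "ATG") {
  x <- seq_chars(orf_segment)
  x[x == "U"] <- "T"
  src <- x
  n <- length(x)
  if (n %% 3 != 0) {
    stop("segment length (", n, ") is not divisible by 3", call. = FALSE)
  }
  stop_period_codons <- as.integer(stop_period_codons)
  if (stop_period_codons < 1) stop("stop_period_codons must be >= 1", call. = FALSE)
  frames_scanned <- sort(unique(as.integer(frames_scanned)))
  stopifnot(all(frames_scanned %in% 0:2))
  n_codons <- n %/% 3

  edits <- list()
  log_edit <- function(pos, new, reason) {
    edits[[length(edits) + 1]] <<- data.frame(
      position = pos, old = x[pos], new = new, reason = reason,
      stringsAsFactors = FALSE)
    x[pos] <<- new
  }

  protected <- integer(0)
  n_stop_events <- 0L

  # would placing `base` at `pos` leave a start codon in a scanned frame
  # overlapping pos?
  creates_start <- function(pos, base) {
    old <- x[pos]; x[pos] <<- base
    found <- FALSE
    for (s in max(1L, pos - 2L):min(n - 2L, pos)) {
      if ((s - 1L) %% 3L %in% frames_scanned &&
          paste(x[s:(s + 2L)], collapse = "") %in% start_codons) {
        found <- TRUE; break
      }
    }
    x[pos] <<- old
    found
  }
  # would a matching SD 4-mer containing pos remain after placing base?
  # (matches elsewhere in a long motif are handled by later passes)
  sd_kmers <- unique(vapply(1:3, function(i) substr(SD_CANONICAL, i, i + 3),
                            character(1)))
  leaves_sd <- function(pos, base) {
    old <- x[pos]; x[pos] <<- base
    found <- FALSE
    for (s in max(1L, pos - 3L):min(n - 3L, pos)) {
      if (paste(x[s:(s + 3L)], collapse = "") %in% sd_kmers) {
        found <- TRUE; break
      }
    }
    x[pos] <<- old
    found
  }

  t_drift <- function() sum(x == "T") - sum(src == "T")

  # pick, among valid (position, base) substitutions, the one keeping the
  # running T count closest to the source; deterministic tie-break by
  # candidate order (positions ascending, bases T, A, C, G)
  # T imbalance of the mimic vs the source within a 55-nt neighbourhood of
  # pos; used so edits also repair the *local* U-content profile
  local_drift <- function(pos) {
    lo <- max(1L, pos - 27L); hi <- min(n, pos + 27L)
    sum(x[lo:hi] == "T") - sum(src[lo:hi] == "T")
  }

  best_substitution <- function(positions, valid, reason) {
    drift <- t_drift()
    best <- NULL
    for (pos in positions) {
      if (pos %in% protected) next
      for (base in c("T", "A", "C", "G")) {
        if (base == x[pos]) next
        if (!valid(pos, base)) next
        delta <- (base == "T") - (x[pos] == "T")
        score <- c(abs(local_drift(pos) + delta), abs(drift + delta))
        if (is.null(best) ||
            score[1] < best$score[1] ||
            (score[1] == best$score[1] && score[2] < best$score[2])) {
          best <- list(pos = pos, base = base, score = score)
        }
      }
    }
    if (is.null(best)) return(FALSE)
    log_edit(best$pos, best$base, reason)
    TRUE
  }

  destroy_codon <- function(p, reason) {
    best_substitution(p:(p + 2L), function(pos, base) {
      old <- x[pos]; x[pos] <<- base
      still <- paste(x[p:(p + 2L)], collapse = "") %in% start_codons
      x[pos] <<- old
      !still && !creates_start(pos, base)
    }, reason)
  }

  # -- stop decoration: TAA at codons stop_period-1, 2*stop_period-1, ... (0-based).
  # Each event may change up to 3 bases; when writing TAA costs T locally and
  # budget remains, the event spends it on a nearby compensating T so the
  # windowed U-profile tracks the source.
  stop_codon_idx <- if (n_codons >= stop_period_codons) {
    seq.int(stop_period_codons, n_codons, by = stop_period_codons)
  } else {
    integer(0)
  }
  for (ci in stop_codon_idx) {
    p <- 3L * (ci - 1L) + 1L
    codon <- paste(x[p:(p + 2L)], collapse = "")
    if (!codon %in% STOP_CODONS) {
      n_stop_events <- n_stop_events + 1L
      n_changed <- 0L
      for (k in 0:2) {
        if (x[p + k] != c("T", "A", "A")[k + 1]) {
          log_edit(p + k, c("T", "A", "A")[k + 1], "stop_insertion")
          n_changed <- n_changed + 1L
        }
      }
      protected <- c(protected, p:(p + 2L))
      # spend the event's remaining base budget repairing the local T balance
      # (which may have been dented by this or a neighbouring stop write)
      while (n_changed < 3L) {
        ld <- local_drift(p + 1L)
        if (ld == 0L) break
        want <- if (ld < 0L) "T" else "A"
        comp <- NA_integer_
        for (off in 1:27) {
          for (pos in c(p - off, p + 2L + off)) {
            if (pos < 1L || pos > n || pos %in% protected) next
            if (ld < 0L && x[pos] == "T") next
            if (ld > 0L && x[pos] != "T") next
            if (creates_start(pos, want) || leaves_sd(pos, want)) next
            comp <- pos; break
          }
          if (!is.na(comp)) break
        }
        if (is.na(comp)) break
        log_edit(comp, want, "stop_insertion")
        n_changed <- n_changed + 1L
      }
    } else {
      protected <- c(protected, p:(p + 2L))
    }
  }

  # -- start removal; stop writes can juxtapose new starts, so iterate
  for (pass in 1:10) {
    found_any <- FALSE
    for (f in frames_scanned) {
      for (p in frame_codon_positions(x, f, start_codons)) {
        # a neighbouring edit may already have destroyed this start
        if (!paste(x[p:(p + 2L)], collapse = "") %in% start_codons) next
        found_any <- TRUE
        if (!destroy_codon(p, "start_removal")) {
          stop("cannot destroy start codon at position ", p,
               " without creating another; pathological input", call. = FALSE)
        }
      }
    }
    if (!found_any) break
  }

  # -- Shine-Dalgarno disruption: remove every >= 4-base AGGAGG match
  for (pass in 1:100) {
    motifs <- find_sd_motifs(x)
    if (nrow(motifs) == 0) break
    m <- motifs[1, ]
    done <- best_substitution(m$start:m$end, function(pos, base) {
      !creates_start(pos, base) && !leaves_sd(pos, base)
    }, "sd_disruption")
    if (!done) {
      stop("cannot disrupt SD-like motif at position ", m$start, call. = FALSE)
    }
  }

  # 2 T per 100 nt, floored at one event's worth (3 bases) so short inputs
  # whose single forced stop write moves T are not spuriously flagged
  t_src <- sum(src == "T"); t_mimic <- sum(x == "T")
  if (abs(t_mimic - t_src) > max(3, 2 * n / 100)) {
    warning("mimic T count drifted by ", t_mimic - t_src, " over ", n,
            " nt (budget 2 per 100 nt)", call. = FALSE)
  }

  edits <- if (length(edits) > 0) {
    do.call(rbind, edits)
  } else {
    data.frame(position = integer(0), old = character(0),
               new = character(0), reason = character(0))
  }
  report <- verify_untranslatable(paste(x, collapse = ""),
                                  frames = frames_scanned,
                                  start_codons = start_codons)
  report$n_stop_events <- n_stop_events
  report$t_count_source <- t_src
  report$t_count_mimic <- t_mimic

  structure(list(
    source_sequence = paste(src, collapse = ""),
    mimic_sequence = paste(x, collapse = ""),
    edits = edits,
    report = report),
    class = "mimic_design")
}

#' @export
print.mimic_design <- function(x, ...) {
  cat("Untranslatable mimic design (", nchar(x$mimic_sequence), " nt)\n", sep = "")
  cat("  edits:", nrow(x$edits),
      "(", sum(x$edits$reason == "start_removal"), "start removals,",
      x$report$n_stop_events, "stop writes,",
      sum(x$edits$reason == "sd_disruption"), "SD disruptions )\n")
  cat("  T count:", x$report$t_count_source, "->", x$report$t_count_mimic, "\n")
  invisible(x)
}
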