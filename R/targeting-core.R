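revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Match an observed sequence against an IUPAC PAM pattern
#'
#' True iff every observed base lies in the degeneracy set of the
#' corresponding pattern code. Any non-ACGT character in `observed`
#' (including N) fails the match: an ambiguous genome base cannot be
#' certified to satisfy the PAM.
#'
#' @param pattern IUPAC pattern string (validated).
#' @param observed nucleotide string of the same length.
#' @return Logical scalar.
#' @examples
#' match_pam("NGG", "AGG")
#' match_pam("TTTV", "TTTT")  # FALSE: V excludes T
#' @export
match_pam <- function(pattern, observed) {
  pattern <- toupper(pattern); observed <- toupper(observed)
  if (nchar(pattern) != nchar(observed))
    stop("PAM pattern and observed sequence differ in length (",
         nchar(pattern), " vs ", nchar(observed), ")", call. = FALSE)
  pc <- strsplit(pattern, "")[[1]]
  bad <- setdiff(pc, names(IUPAC_SETS))
  if (length(bad))
    stop("invalid IUPAC code(s) in pattern: ", paste(bad, collapse = ", "),
         call. = FALSE)
  oc <- strsplit(observed, "")[[1]]
  if (!all(oc %in% c("A", "C", "G", "T"))) return(FALSE)
  all(mapply(function(p, o) o %in% IUPAC_SETS[[p]], pc, oc))
}

empty_guide_frame <- function() {
  data.frame(editor = character(0), strand = character(0),
             protospacer_start = integer(0), protospacer_end = integer(0),
             spacer_seq = character(0), pam_seq = character(0),
             window_pos = integer(0), bystanders = character(0),
             n_bystanders = integer(0), preferential = logical(0),
             stringsAsFactors = FALSE)
}

#' Enumerate valid guide placements for one flanked target
#'
#' Slides the editing window over the target cytosine: for every protospacer
#' position `p` in `[window_start, window_end]` the protospacer is placed so
#' that the target C sits at position `p`, the PAM is read immediately 3' of
#' the protospacer (`pam_side == "three_prime"`) or immediately 5'
#' (`"five_prime"`), and a candidate is emitted for every in-bounds placement
#' whose PAM matches. All coordinates in the returned table are 0-based
#' half-open intervals on the plus strand of the flank sequence; the spacer
#' is reported 5'\eqn{\rightarrow}3' on the protospacer strand (the sequence
#' one orders as the gRNA spacer).
#'
#' Bystanders are the other cytosines, on the target strand, at window
#' positions different from the target's; a candidate with none is
#' preferential. Placements touching non-ACGT genome characters are rejected
#' and tallied in the `rejected_ambiguous` attribute.
#'
#' @param target a `flanked_target` (see [extract_flank()] /
#'   [flanked_target()]).
#' @param editor an `editor_spec`.
#' @return A data.frame of guide candidates ordered by window position, with
#'   attribute `rejected_ambiguous` (count of placements dropped for
#'   ambiguity codes).
#' @export
enumerate_guides <- function(target, editor) {
  stopifnot(inherits(target, "flanked_target"),
            inherits(editor, "editor_spec"))
  seq_plus <- target$sequence
  n <- nchar(seq_plus)
  # target-strand view: the strand on which the editable base reads C
  if (target$target_strand == "+") {
    s <- toupper(seq_plus)
    t0 <- target$target_offset
  } else {
    s <- revcomp(seq_plus)
    t0 <- n - 1L - target$target_offset
  }
  if (substr(s, t0 + 1L, t0 + 1L) != "C")
    stop("flanked target does not read C on its target strand", call. = FALSE)
  L <- editor$spacer_length
  plen <- nchar(editor$pam_pattern)
  sc <- strsplit(s, "")[[1]]
  rows <- list()
  rejected <- 0L
  for (p in editor$window_start:editor$window_end) {
    a <- t0 - (p - 1L)              # 0-based protospacer start in s
    if (a < 0L || a + L > n) next
    pam_at <- if (editor$pam_side == "three_prime") a + L else a - plen
    if (pam_at < 0L || pam_at + plen > n) next
    proto <- substr(s, a + 1L, a + L)
    pam <- substr(s, pam_at + 1L, pam_at + plen)
    if (grepl("[^ACGT]", proto) || grepl("[^ACGT]", pam)) {
      rejected <- rejected + 1L
      next
    }
    if (!match_pam(editor$pam_pattern, pam)) next
    win <- editor$window_start:editor$window_end
    bys <- win[win != p & sc[a + win] == "C"]
    # map protospacer interval back to plus-strand flank coordinates
    if (target$target_strand == "+") {
      ps <- a
    } else {
      ps <- n - (a + L)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      editor = editor$name, strand = target$target_strand,
      protospacer_start = ps, protospacer_end = ps + L,
      spacer_seq = proto, pam_seq = pam, window_pos = p,
      bystanders = paste(bys, collapse = ","),
      n_bystanders = length(bys), preferential = length(bys) == 0L,
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty_guide_frame()
  rownames(out) <- NULL
  attr(out, "rejected_ambiguous") <- rejected
  out
}

#' Is a guide candidate preferential?
#'
#' A candidate is preferential when the target cytosine is the only cytosine
#' in the editing window, i.e. it has no bystanders.
#'
#' @param candidate one row of an [enumerate_guides()] table (or a list with
#'   a `bystanders`/`n_bystanders` field).
#' @return Logical scalar.
#' @export
classify_preferential <- function(candidate) {
  if (!is.null(candidate$n_bystanders))
    return(as.integer(candidate$n_bystanders[1]) == 0L)
  b <- candidate$bystanders
  is.null(b) || !nzchar(paste(b, collapse = ","))
}

#' Assess one variant against an editor panel
#'
#' Extracts the flank, enumerates guides for every panel editor, and collects
#' per-editor targetability. An editor is *targetable* for the variant iff it
#' has at least one valid candidate, and *preferential* iff at least one of
#' its candidates is bystander-free (rule `"any"`; set
#' `preferential_rule = "all"` to require every candidate bystander-free).
#'
#' @param record a `variant_record` (see [variant_record()]).
#' @param genome a `DNAStringSet` or `Rsamtools::FaFile` (or FASTA path).
#' @param panel an `editor_panel`.
#' @param flank flank half-width in nt; widened automatically when too
#'   narrow for some panel editor.
#' @param preferential_rule "any" (default) or "all".
#' @return A `targetability_report`: list with `variant_id`, `edit_class`,
#'   `candidates` (one data.frame over all editors), `targetable_editors`,
#'   `preferential_editors`, `any_targetable`.
#' @export
assess_variant <- function(record, genome, panel, flank = 30L,
                           preferential_rule = c("any", "all")) {
  preferential_rule <- match.arg(preferential_rule)
  stopifnot(inherits(panel, "editor_panel"))
  cls <- classify_edit(record)
  if (cls == "not_applicable")
    stop("variant ", record$variant_id,
         " is neither a C-to-T/G-to-A nor a T-to-C/A-to-G SNV", call. = FALSE)
  flank <- check_flank(flank, panel)
  target <- extract_flank(genome, record, cls, flank = flank)
  assess_target(target, panel, variant_id = record$variant_id,
                edit_class = cls, preferential_rule = preferential_rule)
}

assess_target <- function(target, panel, variant_id = NA_character_,
                          edit_class = NA_character_,
                          preferential_rule = "any") {
  cand <- lapply(panel$editors, function(e) enumerate_guides(target, e))
  cand_df <- do.call(rbind, c(cand, make.row.names = FALSE))
  if (is.null(cand_df)) cand_df <- empty_guide_frame()
  tgt <- names(panel$editors)[vapply(cand, nrow, integer(1)) > 0L]
  pref_of <- function(df) {
    if (!nrow(df)) return(FALSE)
    if (preferential_rule == "any") any(df$preferential) else
      all(df$preferential)
  }
  pref <- names(panel$editors)[vapply(cand, pref_of, logical(1))]
  structure(list(variant_id = variant_id, edit_class = edit_class,
                 target = target, candidates = cand_df,
                 targetable_editors = tgt, preferential_editors = pref,
                 any_targetable = length(tgt) > 0L),
            class = "targetability_report")
}

#' @export
print.targetability_report <- function(x, ...) {
  cat(sprintf("<targetability_report> %s (%s): %d candidate(s), %d/%s editors targetable\n",
              x$variant_id, x$edit_class, nrow(x$candidates),
              length(x$targetable_editors),
              if (x$any_targetable) paste(x$targetable_editors, collapse = ",")
              else "none"))
  invisible(x)
}

#' Combine per-editor verdicts across a panel selection
#'
#' Union: a variant is flagged iff targetable by at least one selected
#' editor. Intersection: iff targetable by all of them. The same rule is
#' applied to preferential flags.
#'
#' @param reports list of `targetability_report`s over the same panel.
#' @param mode "union" or "intersection".
#' @param editors editor names to combine over, or `"all"` for every editor
#'   seen in the reports.
#' @return data.frame with columns `variant_id`, `targetable`,
#'   `preferential`.
#' @export
combine_panel <- function(reports, mode = c("union", "intersection"),
                          editors = "all") {
  mode <- match.arg(mode)
  stopifnot(length(reports) > 0)
  all_editors <- unique(unlist(lapply(reports, function(r)
    unique(r$candidates$editor))))
  if (identical(editors, "all")) {
    # combine over the full panel the reports were computed against when
    # recorded, else over editors observed
    editors <- attr(reports, "panel_editors")
    if (is.null(editors)) editors <- all_editors
  }
  if (!length(editors)) stop("empty editor selection", call. = FALSE)
  comb <- function(hits) {
    if (mode == "union") length(intersect(hits, editors)) > 0L
    else all(editors %in% hits)
  }
  data.frame(
    variant_id = vapply(reports, `[[`, character(1), "variant_id"),
    targetable = vapply(reports, function(r) comb(r$targetable_editors),
                        logical(1)),
    preferential = vapply(reports, function(r) comb(r$preferential_editors),
                          logical(1)),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-editor and any-editor targetability statistics
#'
#' Counts, over a set of variant reports, how many variants each editor can
#' target (and target preferentially), plus the "any editor" aggregate — the
#' headline \dQuote{fraction of pathogenic SNVs editable by at least one
#' base editor} statistic.
#'
#' @param reports list of `targetability_report`s.
#' @param editors editor name vector; defaults to the panel recorded with
#'   the reports, else every editor observed.
#' @return data.frame with one row per editor plus a final `"any"` row:
#'   columns `editor`, `n_targetable`, `n_preferential`,
#'   `frac_targetable`, `frac_preferential`; attribute `n_variants`.
#' @export
panel_statistics <- function(reports, editors = NULL) {
  stopifnot(length(reports) > 0)
  if (is.null(editors)) {
    editors <- attr(reports, "panel_editors")
    if (is.null(editors))
      editors <- unique(unlist(lapply(reports, `[[`, "targetable_editors")))
  }
  n <- length(reports)
  tgt <- lapply(reports, `[[`, "targetable_editors")
  prf <- lapply(reports, `[[`, "preferential_editors")
  nt <- vapply(editors, function(e)
    sum(vapply(tgt, function(x) e %in% x, logical(1))), integer(1))
  np <- vapply(editors, function(e)
    sum(vapply(prf, function(x) e %in% x, logical(1))), integer(1))
  any_t <- sum(vapply(tgt, function(x) length(x) > 0L, logical(1)))
  any_p <- sum(vapply(prf, function(x) length(x) > 0L, logical(1)))
  out <- data.frame(
    editor = c(editors, "any"),
    n_targetable = c(nt, any_t),
    n_preferential = c(np, any_p),
    stringsAsFactors = FALSE, row.names = NULL)
  out$frac_targetable <- out$n_targetable / n
  out$frac_preferential <- out$n_preferential / n
  attr(out, "n_variants") <- n
  out
}

#' Scan a free sequence for all editable cytosines and guanines
#'
#' Every C on the plus strand and every G (a C on the minus strand) is tried
#' as a base-editing target against the given editors. Coordinates in the
#' result are 0-based, plus-strand, half-open over the input sequence;
#' `target_index` is the 0-based position of the editable base.
#'
#' @param seq nucleotide string (A/C/G/T only).
#' @param editors an `editor_panel` or a single `editor_spec`.
#' @return data.frame of candidates with columns `target_index`,
#'   `target_base` plus the [enumerate_guides()] columns.
#' @export
scan_sequence <- function(seq, editors) {
  if (inherits(editors, "editor_spec"))
    editors <- new_editor_panel(list(editors))
  stopifnot(inherits(editors, "editor_panel"))
  seq <- toupper(seq)
  chars <- strsplit(seq, "")[[1]]
  bad <- which(!chars %in% c("A", "C", "G", "T"))
  if (length(bad))
    stop("non-nucleotide character(s) at position(s): ",
         paste(utils::head(bad, 20), collapse = ", "), call. = FALSE)
  min_need <- min(vapply(editors$editors, function(e)
    e$spacer_length + nchar(e$pam_pattern), integer(1)))
  if (nchar(seq) < min_need)
    stop("sequence shorter than the smallest spacer+PAM (", min_need, " nt)",
         call. = FALSE)
  hits <- which(chars %in% c("C", "G"))
  out <- list()
  for (i in hits) {
    strand <- if (chars[i] == "C") "+" else "-"
    tgt <- flanked_target(seq, i - 1L, strand)
    for (e in editors$editors) {
      df <- enumerate_guides(tgt, e)
      if (nrow(df)) {
        df$target_index <- i - 1L
        df$target_base <- chars[i]
        out[[length(out) + 1L]] <- df
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else {
    ef <- empty_guide_frame(); ef$target_index <- integer(0)
    ef$target_base <- character(0); ef
  }
  rownames(res) <- NULL
  front <- c("target_index", "target_base")
  res[, c(front, setdiff(names(res), front))]
}

# flank must reach the farthest editor geometry; widen with a message if not
check_flank <- function(flank, panel) {
  need <- max(vapply(panel$editors, function(e)
    e$spacer_length + nchar(e$pam_pattern) - 1L, integer(1)))
  if (flank < need) {
    message("flank ", flank, " nt too narrow for panel (need >= ", need,
            "); widening to ", need)
    flank <- need
  }
  as.integer(flank)
}
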