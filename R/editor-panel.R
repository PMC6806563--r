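IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

PAM_SIDES <- c("three_prime", "five_prime")

#' Define a base-editor targeting geometry
#'
#' An editor spec captures everything the targeting algorithm needs to know
#' about one cytosine base editor: its PAM pattern (IUPAC codes allowed),
#' which side of the protospacer the PAM sits on, the spacer length, and the
#' editing window expressed in protospacer coordinates.
#'
#' Protospacer positions are always counted 5'\eqn{\rightarrow}3' along the
#' protospacer with position 1 at the 5'-most base. This single convention
#' covers both families: for a 3'-PAM (Cas9-type) editor position 1 is the
#' PAM-distal base, and for a 5'-PAM (Cpf1/Cas12a-type) editor position 1 is
#' the PAM-proximal base.
#'
#' @param name short identifier, unique within a panel.
#' @param pam_pattern IUPAC nucleotide string, e.g. "NGG" or "TTTV".
#' @param pam_side "three_prime" (Cas9 family) or "five_prime" (Cpf1 family).
#' @param spacer_length protospacer/spacer length in nt.
#' @param window_start,window_end editing-window bounds, 1-based protospacer
#'   positions with `1 <= window_start <= window_end <= spacer_length`.
#' @param citation free-text provenance label for the geometry.
#' @return An object of class `editor_spec`.
#' @examples
#' editor_spec("BE3", "NGG", "three_prime", 20, 4, 8)
#' @export
editor_spec <- function(name, pam_pattern, pam_side, spacer_length,
                        window_start, window_end, citation = "") {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("editor 'name' must be a non-empty string", call. = FALSE)
  pam_pattern <- toupper(as.character(pam_pattern))
  if (length(pam_pattern) != 1L || !nzchar(pam_pattern))
    stop("'pam_pattern' must be a non-empty string (editor '", name, "')",
         call. = FALSE)
  pam_chars <- strsplit(pam_pattern, "")[[1]]
  bad <- setdiff(pam_chars, names(IUPAC_SETS))
  if (length(bad))
    stop("'pam_pattern' of editor '", name,
         "' contains non-IUPAC code(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (!is.character(pam_side) || length(pam_side) != 1L ||
      !pam_side %in% PAM_SIDES)
    stop("'pam_side' of editor '", name, "' must be one of: ",
         paste(PAM_SIDES, collapse = ", "), call. = FALSE)
  spacer_length <- as.integer(spacer_length)
  window_start <- as.integer(window_start)
  window_end <- as.integer(window_end)
  for (f in c("spacer_length", "window_start", "window_end")) {
    v <- get(f)
    if (length(v) != 1L || is.na(v))
      stop("'", f, "' of editor '", name, "' must be a single integer",
           call. = FALSE)
  }
  if (!(1L <= window_start && window_start <= window_end &&
        window_end <= spacer_length))
    stop("editor '", name, "': need 1 <= window_start <= window_end <= ",
         "spacer_length, got window ", window_start, "..", window_end,
         " with spacer_length ", spacer_length, call. = FALSE)
  structure(
    list(name = name, pam_pattern = pam_pattern, pam_side = pam_side,
         spacer_length = spacer_length, window_start = window_start,
         window_end = window_end, citation = as.character(citation)),
    class = "editor_spec")
}

#' Define a custom editor from raw geometry
#'
#' Convenience wrapper mirroring the "define a specific PAM sequence, editing
#' window, and spacer length" workflow: builds a validated [editor_spec()]
#' named `"custom"` (or as given) usable anywhere a panel editor is.
#'
#' @inheritParams editor_spec
#' @return An `editor_spec`.
#' @examples
#' make_custom_editor("NG", "three_prime", 20, 4, 8)
#' @export
make_custom_editor <- function(pam_pattern, pam_side, spacer_length,
                               window_start, window_end, name = "custom") {
  editor_spec(name, pam_pattern, pam_side, spacer_length,
              window_start, window_end, citation = "user-defined")
}

#' @export
print.editor_spec <- function(x, ...) {
  cat(sprintf("<editor_spec> %s: PAM %s (%s), spacer %d nt, window %d-%d\n",
              x$name, x$pam_pattern,
              if (x$pam_side == "three_prime") "3'" else "5'",
              x$spacer_length, x$window_start, x$window_end))
  invisible(x)
}

new_editor_panel <- function(editors, combine_mode = "union") {
  if (!length(editors)) stop("panel must contain at least one editor",
                             call. = FALSE)
  stopifnot(all(vapply(editors, inherits, logical(1), "editor_spec")))
  nms <- vapply(editors, `[[`, character(1), "name")
  if (anyDuplicated(nms))
    stop("duplicate editor name(s) in panel: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "), call. = FALSE)
  names(editors) <- nms
  if (!combine_mode %in% c("union", "intersection"))
    stop("combine_mode must be 'union' or 'intersection'", call. = FALSE)
  structure(list(editors = editors, combine_mode = combine_mode),
            class = "editor_panel")
}

#' Load an editor panel from a config file
#'
#' Reads a tab-separated editor config (columns `name`, `pam_pattern`,
#' `pam_side`, `spacer_length`, `window_start`, `window_end`, `citation`) and
#' validates every entry. With no argument, loads the bundled default panel
#' of 20 published cytosine base editors.
#'
#' @param config_source path to a panel TSV, or `NULL` for the bundled panel.
#' @param combine_mode default verdict combination across editors,
#'   "union" or "intersection".
#' @return An object of class `editor_panel`.
#' @examples
#' panel <- load_panel()
#' length(panel$editors)
#' @export
load_panel <- function(config_source = NULL, combine_mode = "union") {
  if (is.null(config_source))
    config_source <- system.file("extdata", "editor_panel.tsv",
                                 package = "bescan", mustWork = TRUE)
  tab <- utils::read.table(config_source, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "#")
  need <- c("name", "pam_pattern", "pam_side", "spacer_length",
            "window_start", "window_end")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("panel config is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (is.null(tab$citation)) tab$citation <- ""
  editors <- lapply(seq_len(nrow(tab)), function(i)
    editor_spec(tab$name[i], tab$pam_pattern[i], tab$pam_side[i],
                tab$spacer_length[i], tab$window_start[i], tab$window_end[i],
                tab$citation[i]))
  new_editor_panel(editors, combine_mode)
}

#' Serialize a panel back to its config format
#'
#' Writes (or returns) the tab-separated representation read by
#' [load_panel()]; `load_panel(serialize_panel(p, f))` reproduces every field.
#'
#' @param panel an `editor_panel`.
#' @param path output path; if `NULL` the data.frame is returned instead.
#' @return The panel as a data.frame (invisibly when written to `path`).
#' @export
serialize_panel <- function(panel, path = NULL) {
  stopifnot(inherits(panel, "editor_panel"))
  df <- do.call(rbind, lapply(panel$editors, function(e)
    data.frame(name = e$name, pam_pattern = e$pam_pattern,
               pam_side = e$pam_side, spacer_length = e$spacer_length,
               window_start = e$window_start, window_end = e$window_end,
               citation = e$citation, stringsAsFactors = FALSE)))
  rownames(df) <- NULL
  if (is.null(path)) return(df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Subset a panel by editor name
#'
#' @param panel an `editor_panel`.
#' @param names editor names to keep, or `"all"`.
#' @return An `editor_panel` restricted to the selection.
#' @export
select_editors <- function(panel, names = "all") {
  stopifnot(inherits(panel, "editor_panel"))
  if (identical(names, "all")) return(panel)
  unknown <- setdiff(names, names(panel$editors))
  if (length(unknown))
    stop("unknown editor name(s): ", paste(unknown, collapse = ", "),
         "; valid names: ", paste(names(panel$editors), collapse = ", "),
         call. = FALSE)
  new_editor_panel(panel$editors[names], panel$combine_mode)
}

#' @export
print.editor_panel <- function(x, ...) {
  cat(sprintf("<editor_panel> %d editors (combine: %s)\n",
              length(x$editors), x$combine_mode))
  print(serialize_panel(x))
  invisible(x)
}
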