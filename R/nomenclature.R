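# Fatty-acid shorthand nomenclature: parsing, formatting, classification.
#
# The shorthand grammar accepted is `C<carbons>:<double_bonds>[n<pos>][c|t]`,
# e.g. "C16:0", "C20:5n3", "C18:1n9t". Whitespace around the code is ignored.
# Double-bond positional (delta) lists, branched chains and hydroxy acids are
# out of scope.

#' Parse a fatty-acid shorthand code
#'
#' Converts a shorthand code such as `"C20:5n3"` into a structured descriptor
#' holding chain length, number of double bonds, omega class and geometry.
#'
#' The accepted grammar is `C<int>:<int>[n<int>][c|t]` (case of the leading
#' `C` and the `n` is tolerated in lower/upper form; surrounding whitespace is
#' trimmed). The `n<int>` suffix encodes the omega class: `n3`, `n6` and `n9`
#' map to the corresponding class tags, any other position parses but is
#' tagged `"unspecified"` with a warning. A trailing `c` or `t` marks cis or
#' trans geometry; codes without the suffix have geometry `"unspecified"` and
#' are never counted as trans.
#'
#' @param code character scalar, the shorthand code as printed.
#' @param common_name optional free-text trivial name carried as metadata; it
#'   is never used to infer structure.
#' @return An object of class `fa_descriptor`: a list with elements `code`
#'   (canonical shorthand), `carbons`, `double_bonds`, `omega` (`"n3"`,
#'   `"n6"`, `"n9"` or `"unspecified"`), `geometry` (`"cis"`, `"trans"` or
#'   `"unspecified"`) and `common_name`.
#' @examples
#' parse_fa("C20:5n3")   # EPA: 20 carbons, 5 double bonds, omega-3
#' parse_fa("C18:1n9t")  # elaidic acid: trans MUFA
#' parse_fa("C16:0")     # palmitic acid: saturated
#' @seealso [format_fa()], [saturation_class()], [polyene_class()]
#' @export
parse_fa <- function(code, common_name = NULL) {
  if (!is.character(code) || length(code) != 1L || is.na(code)) {
    stop_parse(code, "code must be a single character string")
  }
  raw <- trimws(code)
  m <- regexec("^[Cc]([0-9]+):([0-9]+)(?:[nN]([0-9]+))?([ct])?$", raw)
  parts <- regmatches(raw, m)[[1L]]
  if (length(parts) == 0L) {
    # name the offending token: the first chunk that breaks the grammar
    tok <- if (!grepl("^[Cc]", raw)) {
      substr(raw, 1L, 1L)
    } else if (!grepl(":", raw, fixed = TRUE)) {
      "missing ':'"
    } else {
      sub("^[Cc][0-9]*:?", "", raw)
    }
    stop_parse(raw, sprintf("malformed shorthand (offending token: %s)",
                            if (nzchar(tok)) dQuote(tok, FALSE) else "empty"))
  }
  carbons <- as.integer(parts[2L])
  dbl <- as.integer(parts[3L])
  if (carbons < 2L) {
    stop_parse(raw, sprintf("chain length %d below the minimum of 2", carbons))
  }
  if (dbl > (carbons - 2L) %/% 2L) {
    stop_parse(raw, sprintf(
      "%d double bonds not representable on a C%d chain (max %d)",
      dbl, carbons, (carbons - 2L) %/% 2L))
  }
  omega_pos <- parts[4L]
  geom_code <- parts[5L]
  if (dbl == 0L && (nzchar(omega_pos) || nzchar(geom_code))) {
    stop_parse(raw, "saturated code cannot carry an omega or geometry suffix")
  }
  omega <- "unspecified"
  if (nzchar(omega_pos)) {
    if (omega_pos %in% c("3", "6", "9")) {
      omega <- paste0("n", omega_pos)
    } else {
      warning(sprintf("omega position n%s in %s has no class tag; treated as unspecified",
                      omega_pos, dQuote(raw, FALSE)), call. = FALSE)
    }
  }
  geometry <- switch(geom_code, c = "cis", t = "trans", "unspecified")
  d <- structure(
    list(code = NA_character_, carbons = carbons, double_bonds = dbl,
         omega = omega, geometry = geometry,
         common_name = if (is.null(common_name)) NA_character_ else as.character(common_name)),
    class = "fa_descriptor")
  d$code <- format_fa(d)
  d
}

#' Format a descriptor back to canonical shorthand
#'
#' Regenerates the shorthand code from the structured fields; parsing the
#' result gives back an identical descriptor (round-trip invariant).
#'
#' @param d an `fa_descriptor`.
#' @return character scalar, e.g. `"C18:1n9t"`.
#' @export
format_fa <- function(d) {
  stopifnot(inherits(d, "fa_descriptor"))
  code <- sprintf("C%d:%d", d$carbons, d$double_bonds)
  if (d$omega != "unspecified") code <- paste0(code, d$omega)
  if (d$geometry == "cis")   code <- paste0(code, "c")
  if (d$geometry == "trans") code <- paste0(code, "t")
  code
}

#' @export
format.fa_descriptor <- function(x, ...) format_fa(x)

#' @export
print.fa_descriptor <- function(x, ...) {
  cat(sprintf("<fatty acid %s: C%d, %d double bond%s, omega %s, %s%s>\n",
              x$code, x$carbons, x$double_bonds,
              if (x$double_bonds == 1L) "" else "s",
              x$omega, x$geometry,
              if (is.na(x$common_name)) "" else paste0(" (", x$common_name, ")")))
  invisible(x)
}

#' Saturation class of a fatty acid
#'
#' Classifies by double-bond count: saturated (SFA, 0 bonds), monounsaturated
#' (MUFA, 1) or polyunsaturated (PUFA, 2 or more). The three classes partition
#' every valid descriptor.
#'
#' @param x an `fa_descriptor` or a shorthand code string.
#' @return character scalar: `"SFA"`, `"MUFA"` or `"PUFA"`.
#' @examples
#' saturation_class("C16:0")   # "SFA"
#' saturation_class("C16:1")   # "MUFA"
#' saturation_class("C20:4n6") # "PUFA"
#' @export
saturation_class <- function(x) {
  d <- as_fa(x)
  if (d$double_bonds == 0L) "SFA" else if (d$double_bonds == 1L) "MUFA" else "PUFA"
}

#' Polyene class of a fatty acid
#'
#' The unsaturation-index formula weights each unsaturated FA by its number
#' of double bonds, grouped into six classes (monoenoic through hexaenoic).
#' Saturated FAs belong to no class and return `NA`; more than six double
#' bonds falls outside the supported term list and is an error.
#'
#' @param x an `fa_descriptor` or a shorthand code string.
#' @return integer in 1..6, or `NA_integer_` for a saturated FA.
#' @examples
#' polyene_class("C22:6n3") # 6 (hexaenoic, DHA)
#' polyene_class("C18:0")   # NA (saturated)
#' @export
polyene_class <- function(x) {
  d <- as_fa(x)
  if (d$double_bonds == 0L) return(NA_integer_)
  if (d$double_bonds > 6L) {
    stop(errorCondition(
      sprintf("%s has %d double bonds; polyene classes cover 1..6 only",
              d$code, d$double_bonds),
      class = c("lipidqi_unsupported_class_error", "lipidqi_error")))
  }
  d$double_bonds
}

# coerce code string / descriptor
as_fa <- function(x) {
  if (inherits(x, "fa_descriptor")) return(x)
  parse_fa(x)
}

stop_parse <- function(code, msg) {
  stop(errorCondition(
    sprintf("cannot parse fatty-acid code %s: %s",
            dQuote(as.character(code)[1L], FALSE), msg),
    class = c("lipidqi_parse_error", "lipidqi_error")))
}
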