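# Per-sample fatty-acid composition: construction, CSV I/O, aggregation.

#' Construct a fatty-acid profile
#'
#' A profile holds one sample's FA composition as percentages of total FA
#' (the scale GC-MS FAME quantification reports), plus sample metadata.
#' Duplicate codes are rejected; negative percentages are rejected; a total
#' far from 100% (outside 95--105) records a warning but is not an error,
#' since printed composition tables rarely sum exactly to 100.
#'
#' @param codes character vector of shorthand codes (see [parse_fa()]).
#' @param percentages numeric vector, percent of total FA; `NA` marks an FA
#'   reported as not detected (N.D.) and is stored as 0 with an `nd` flag.
#' @param sd optional numeric vector of standard deviations (metadata only;
#'   no uncertainty propagation is performed downstream).
#' @param names optional character vector of trivial names (metadata only).
#' @param sample_id character scalar label for the sample.
#' @param lipid_content optional percent of dry weight (metadata).
#' @return An object of class `fa_profile`: a list with `sample_id`,
#'   `lipid_content`, a data frame `entries` with columns `name`, `code`,
#'   `percentage`, `sd`, `nd`, and a parallel list `descriptors` of
#'   `fa_descriptor` objects.
#' @export
fa_profile <- function(codes, percentages, sd = NULL, names = NULL,
                       sample_id = "sample", lipid_content = NA_real_) {
  codes <- as.character(codes)
  n <- length(codes)
  if (length(percentages) != n) {
    stop_load("codes and percentages differ in length")
  }
  if (is.null(sd)) sd <- rep(NA_real_, n)
  if (is.null(names)) names <- rep(NA_character_, n)
  descriptors <- vector("list", n)
  canon <- character(n)
  for (i in seq_len(n)) {
    d <- tryCatch(parse_fa(codes[i], common_name = names[i]),
                  lipidqi_parse_error = function(e) {
                    stop_load(sprintf("entry %d: %s", i, conditionMessage(e)))
                  })
    descriptors[[i]] <- d
    canon[i] <- d$code
  }
  if (anyDuplicated(canon)) {
    dup <- canon[duplicated(canon)][1L]
    stop_load(sprintf("duplicate fatty-acid code %s", dQuote(dup, FALSE)))
  }
  pct <- as.numeric(percentages)
  nd <- is.na(pct)
  pct[nd] <- 0
  if (any(pct < 0)) {
    stop_load(sprintf("entry %d: negative percentage %g",
                      which(pct < 0)[1L], pct[pct < 0][1L]))
  }
  total <- sum(pct)
  if (n > 0L && (total < 95 || total > 105)) {
    warning(sprintf("profile %s: percentages sum to %.2f, outside [95, 105]",
                    sample_id, total), call. = FALSE)
  }
  structure(
    list(sample_id = as.character(sample_id),
         lipid_content = as.numeric(lipid_content),
         entries = data.frame(name = names, code = canon, percentage = pct,
                              sd = as.numeric(sd), nd = nd,
                              stringsAsFactors = FALSE),
         descriptors = descriptors),
    class = "fa_profile")
}

#' @export
print.fa_profile <- function(x, ...) {
  cat(sprintf("<fa_profile %s: %d fatty acids, total %.2f%%%s>\n",
              x$sample_id, nrow(x$entries), sum(x$entries$percentage),
              if (is.na(x$lipid_content)) ""
              else sprintf(", lipid content %.2f%% w/w", x$lipid_content)))
  print(x$entries, ...)
  invisible(x)
}

#' Read a fatty-acid profile from CSV
#'
#' The canonical format is comma-separated UTF-8 with a header and columns
#' `name,code,percentage[,sd]`. The literal `"N.D."` (or an empty field) in
#' `percentage` marks a not-detected FA, stored as 0 with an `nd` flag. A
#' multi-sample file may carry a `sample` column plus optional
#' `lipid_content`; then `sample_id` selects which sample to load.
#'
#' @param path path to the CSV file.
#' @param sample_id for multi-sample files, which `sample` value to extract;
#'   ignored (used only as the label) for single-sample files.
#' @return An [fa_profile()].
#' @export
read_profile_csv <- function(path, sample_id = NULL) {
  if (!file.exists(path)) stop_load(sprintf("no such file: %s", path))
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character"),
    error = function(e) stop_load(sprintf("%s: %s", path, conditionMessage(e))))
  if (nrow(df) == 0L) stop_load(sprintf("%s: no data rows", path))
  need <- c("code", "percentage")
  if (!all(need %in% names(df))) {
    stop_load(sprintf("%s: missing required column(s) %s", path,
                      paste(setdiff(need, names(df)), collapse = ", ")))
  }
  lipid <- NA_real_
  if ("sample" %in% names(df) && length(unique(df$sample)) > 1L) {
    if (is.null(sample_id)) {
      stop_load(sprintf("%s holds samples %s; pass sample_id to choose one",
                        path, paste(unique(df$sample), collapse = ", ")))
    }
    df <- df[df$sample == sample_id, , drop = FALSE]
    if (nrow(df) == 0L) stop_load(sprintf("no rows for sample %s", sample_id))
  }
  if ("lipid_content" %in% names(df)) {
    lipid <- suppressWarnings(as.numeric(df$lipid_content[1L]))
  }
  parse_pct <- function(x, col) {
    x <- trimws(x)
    out <- rep(NA_real_, length(x))
    keep <- !(x == "" | toupper(x) %in% c("N.D.", "ND", "N.D", "NA"))
    num <- suppressWarnings(as.numeric(x[keep]))
    if (anyNA(num)) {
      bad <- which(keep)[which(is.na(num))[1L]]
      stop_load(sprintf("row %d: non-numeric %s %s", bad, col,
                        dQuote(x[bad], FALSE)))
    }
    out[keep] <- num
    out
  }
  pct <- parse_pct(df$percentage, "percentage")
  neg <- which(!is.na(pct) & pct < 0)
  if (length(neg)) {
    stop_load(sprintf("row %d: negative percentage %g", neg[1L], pct[neg[1L]]))
  }
  sdv <- if ("sd" %in% names(df)) parse_pct(df$sd, "sd") else NULL
  nms <- if ("name" %in% names(df)) {
    n0 <- df$name
    n0[trimws(n0) == ""] <- NA_character_
    n0
  } else NULL
  withCallingHandlers(
    fa_profile(codes = df$code, percentages = pct, sd = sdv,
               names = nms,
               sample_id = if (is.null(sample_id)) {
                 if ("sample" %in% names(df)) df$sample[1L]
                 else tools::file_path_sans_ext(basename(path))
               } else sample_id,
               lipid_content = lipid),
    lipidqi_load_error = function(e) e)
}

#' Write a fatty-acid profile to CSV
#'
#' Inverse of [read_profile_csv()]: N.D. entries are written back as the
#' literal `"N.D."` so that a read/write cycle is lossless.
#'
#' @param p an [fa_profile()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(p, path) {
  stopifnot(inherits(p, "fa_profile"))
  e <- p$entries
  out <- data.frame(
    sample = p$sample_id,
    name = ifelse(is.na(e$name), "", e$name),
    code = e$code,
    percentage = ifelse(e$nd, "N.D.", as.character(e$percentage)),
    sd = ifelse(is.na(e$sd), "", as.character(e$sd)),
    lipid_content = if (is.na(p$lipid_content)) "" else as.character(p$lipid_content),
    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Aggregate a profile into the class sums the index formulas consume
#'
#' Computes every aggregate quantity needed by the nutritional index
#' equations:
#' \itemize{
#'   \item `sfa`, `mufa`, `pufa` -- percent totals by saturation class;
#'   \item `ufa = mufa + pufa` -- all unsaturated FAs, trans isomers
#'     included;
#'   \item `n3`, `n6` -- omega-3 / omega-6 sums restricted to PUFAs (an
#'     omega-9 tag on a MUFA never enters these sums);
#'   \item `tfa` -- sum over entries with explicit trans geometry only;
#'   \item `cis_c18_1` -- C18:1 entries with explicit cis geometry (oleic
#'     acid); the trans isomer is excluded;
#'   \item `polyene` -- percent totals by double-bond count 1..6;
#'   \item `named` -- lookups for the individual FAs the formulas cite
#'     (C12:0, C14:0, C16:0, C18:0, C20:5n3 EPA, C22:6n3 DHA), 0 when
#'     absent.
#' }
#' Not-detected entries contribute exactly 0 everywhere.
#'
#' @param p an [fa_profile()].
#' @return An object of class `fa_groups` (a list of the fields above plus
#'   `total`, the grand sum of entry percentages, and `sample_id`).
#' @examples
#' ref <- diatom_reference_profiles()
#' aggregate_profile(ref$Ano)
#' @export
aggregate_profile <- function(p) {
  stopifnot(inherits(p, "fa_profile"))
  pct <- p$entries$percentage
  dbl <- vapply(p$descriptors, `[[`, integer(1), "double_bonds")
  omega <- vapply(p$descriptors, `[[`, character(1), "omega")
  geom <- vapply(p$descriptors, `[[`, character(1), "geometry")
  carbons <- vapply(p$descriptors, `[[`, integer(1), "carbons")
  code <- p$entries$code

  sfa  <- sum(pct[dbl == 0L])
  mufa <- sum(pct[dbl == 1L])
  pufa <- sum(pct[dbl >= 2L])
  is_pufa <- dbl >= 2L
  polyene <- vapply(1:6, function(k) sum(pct[dbl == k]), numeric(1))
  names(polyene) <- as.character(1:6)

  named_codes <- c("C12:0", "C14:0", "C16:0", "C18:0", "C20:5n3", "C22:6n3")
  named <- vapply(named_codes, function(cc) sum(pct[code == cc]), numeric(1))

  structure(
    list(sample_id = p$sample_id,
         total = sum(pct),
         sfa = sfa, mufa = mufa, pufa = pufa, ufa = mufa + pufa,
         n3 = sum(pct[is_pufa & omega == "n3"]),
         n6 = sum(pct[is_pufa & omega == "n6"]),
         tfa = sum(pct[geom == "trans"]),
         cis_c18_1 = sum(pct[carbons == 18L & dbl == 1L & geom == "cis"]),
         polyene = polyene,
         named = named),
    class = "fa_groups")
}

#' @export
print.fa_groups <- function(x, ...) {
  cat(sprintf("<fa_groups %s (total %.2f%%)>\n", x$sample_id, x$total))
  cat(sprintf("  SFA %.2f  MUFA %.2f  PUFA %.2f  (UFA %.2f)\n",
              x$sfa, x$mufa, x$pufa, x$ufa))
  cat(sprintf("  n-3 %.2f  n-6 %.2f  trans %.2f  cis-C18:1 %.2f\n",
              x$n3, x$n6, x$tfa, x$cis_c18_1))
  invisible(x)
}

#' Export group sums as a plain list (JSON-ready)
#'
#' @param g an `fa_groups` object.
#' @return a named list mirroring the `fa_groups` fields, suitable for
#'   `jsonlite::toJSON()`.
#' @export
groups_as_list <- function(g) {
  stopifnot(inherits(g, "fa_groups"))
  list(sample_id = g$sample_id, total = g$total,
       sfa = g$sfa, mufa = g$mufa, pufa = g$pufa, ufa = g$ufa,
       n3 = g$n3, n6 = g$n6, tfa = g$tfa, cis_c18_1 = g$cis_c18_1,
       polyene = as.list(g$polyene), named = as.list(g$named))
}

stop_load <- function(msg) {
  stop(errorCondition(msg,
                      class = c("lipidqi_load_error", "lipidqi_error")))
}
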