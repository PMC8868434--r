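# Nutritional quality indices computed from fa_groups class sums.
#
# Eight indices are supported, each a function of the aggregates in
# `fa_groups` (all percentages of total FA):
#
#   PS   = PUFA / SFA
#   IA   = [C12:0 + 4*C14:0 + C16:0] / UFA
#   IT   = (C14:0 + C16:0 + C18:0) /
#          [0.5*MUFA + 0.5*n6 + 3*n3 + (n3/n6)]
#   h/H  = (cis-C18:1 + PUFA) / (C12:0 + C14:0 + C16:0)
#   HPI  = UFA / [C12:0 + 4*C14:0 + C16:0]      (reciprocal of IA)
#   UI   = sum over k = 1..6 of k * (% of FAs with k double bonds)
#   SED  = EPA (C20:5n3) + DHA (C22:6n3)
#   TFA  = sum of explicitly trans entries
#
# Single-index functions raise a classed error on an undefined denominator;
# nutritional_indices() flags the offending index instead so that a batch
# run never dies on one degenerate sample.

named_of <- function(g, code) unname(g$named[[code]])

check_groups <- function(g) {
  if (!inherits(g, "fa_groups")) {
    stop("expected an 'fa_groups' object; see aggregate_profile()", call. = FALSE)
  }
  g
}

stop_undefined <- function(index, msg) {
  stop(errorCondition(
    sprintf("index %s is undefined: %s", index, msg),
    class = c("lipidqi_undefined_index_error", "lipidqi_error")))
}

#' PUFA/SFA ratio (PS)
#'
#' Higher values indicate a composition richer in polyunsaturates relative
#' to saturates, the classic dietary cardiovascular quality marker.
#'
#' @param g an `fa_groups` object from [aggregate_profile()].
#' @return numeric scalar.
#' @export
index_ps <- function(g) {
  check_groups(g)
  if (g$sfa <= 0) stop_undefined("PS", "SFA total is zero")
  g$pufa / g$sfa
}

#' Index of atherogenicity (IA)
#'
#' Ratio of the main pro-atherogenic saturates (lauric, four-fold weighted
#' myristic, palmitic) to total unsaturated FAs. Lower is better.
#'
#' @inheritParams index_ps
#' @return numeric scalar.
#' @export
index_ia <- function(g) {
  check_groups(g)
  if (g$ufa <= 0) stop_undefined("IA", "UFA total is zero")
  (named_of(g, "C12:0") + 4 * named_of(g, "C14:0") + named_of(g, "C16:0")) / g$ufa
}

#' Index of thrombogenicity (IT)
#'
#' Pro-thrombotic saturates (myristic, palmitic, stearic) over a weighted
#' sum of protective unsaturates; the final denominator term is the
#' omega-3 to omega-6 ratio. Lower is better.
#'
#' @inheritParams index_ps
#' @return numeric scalar.
#' @export
index_it <- function(g) {
  check_groups(g)
  if (g$n6 <= 0) stop_undefined("IT", "omega-6 PUFA total is zero")
  denom <- 0.5 * g$mufa + 0.5 * g$n6 + 3 * g$n3 + g$n3 / g$n6
  if (denom <= 0) stop_undefined("IT", "denominator is zero")
  (named_of(g, "C14:0") + named_of(g, "C16:0") + named_of(g, "C18:0")) / denom
}

#' Hypocholesterolemic/hypercholesterolemic ratio (h/H)
#'
#' Cholesterol-lowering FAs (cis-oleic acid plus all PUFAs) over the
#' cholesterol-raising saturates (lauric, myristic, palmitic). The trans
#' C18:1 isomer is excluded from the numerator. Higher is better.
#'
#' @inheritParams index_ps
#' @return numeric scalar.
#' @export
index_h_over_h <- function(g) {
  check_groups(g)
  denom <- named_of(g, "C12:0") + named_of(g, "C14:0") + named_of(g, "C16:0")
  if (denom <= 0) stop_undefined("h/H", "C12:0 + C14:0 + C16:0 is zero")
  (g$cis_c18_1 + g$pufa) / denom
}

#' Health-promoting index (HPI)
#'
#' The algebraic reciprocal of the index of atherogenicity. Higher is
#' better.
#'
#' @inheritParams index_ps
#' @return numeric scalar.
#' @export
index_hpi <- function(g) {
  check_groups(g)
  denom <- named_of(g, "C12:0") + 4 * named_of(g, "C14:0") + named_of(g, "C16:0")
  if (denom <= 0) stop_undefined("HPI", "C12:0 + 4*C14:0 + C16:0 is zero")
  g$ufa / denom
}

#' Unsaturation index (UI)
#'
#' Each unsaturated FA's percentage weighted by its double-bond count, from
#' monoenoics (weight 1) to hexaenoics (weight 6); trans isomers are
#' included in their class.
#'
#' @inheritParams index_ps
#' @return numeric scalar (no denominator; always defined).
#' @export
index_ui <- function(g) {
  check_groups(g)
  sum(seq_len(6) * g$polyene)
}

#' Sum of EPA and DHA (SED)
#'
#' Total of eicosapentaenoic (C20:5n3) and docosahexaenoic (C22:6n3) acid
#' percentages, identified by shorthand code.
#'
#' @inheritParams index_ps
#' @return numeric scalar, percent of total FA.
#' @export
index_sed <- function(g) {
  check_groups(g)
  named_of(g, "C20:5n3") + named_of(g, "C22:6n3")
}

#' Total trans fatty acids (TFA)
#'
#' Sum over entries with explicit trans geometry; codes without a geometry
#' suffix never count as trans.
#'
#' @inheritParams index_ps
#' @return numeric scalar, percent of total FA.
#' @export
index_tfa <- function(g) {
  check_groups(g)
  g$tfa
}

#' Compute all eight nutritional indices for a profile
#'
#' Aggregates the profile and evaluates PS, IA, IT, h/H, HPI, UI, SED and
#' TFA. An index whose denominator is zero (possible for degenerate
#' compositions, e.g. all-saturated or all-zero profiles) is reported as
#' `NA` and listed in the `undefined` field instead of aborting the report.
#'
#' @param p an [fa_profile()] (or an `fa_groups` object, in which case the
#'   aggregation step is skipped).
#' @return An object of class `fa_index_report`: list with numeric fields
#'   `ps`, `ia`, `it`, `h_over_h`, `hpi`, `ui`, `sed`, `tfa`, character
#'   vector `undefined` naming flagged indices, `sample_id`, and the
#'   `fa_groups` used under `groups`.
#' @examples
#' ref <- diatom_reference_profiles()
#' nutritional_indices(ref$Rho)
#' @export
nutritional_indices <- function(p) {
  g <- if (inherits(p, "fa_groups")) p else aggregate_profile(p)
  fns <- list(ps = index_ps, ia = index_ia, it = index_it,
              h_over_h = index_h_over_h, hpi = index_hpi,
              ui = index_ui, sed = index_sed, tfa = index_tfa)
  undefined <- character(0)
  vals <- lapply(names(fns), function(nm) {
    tryCatch(fns[[nm]](g),
             lipidqi_undefined_index_error = function(e) {
               undefined <<- c(undefined, nm)
               NA_real_
             })
  })
  names(vals) <- names(fns)
  structure(c(vals,
              list(undefined = undefined, sample_id = g$sample_id, groups = g)),
            class = "fa_index_report")
}

#' @export
print.fa_index_report <- function(x, digits = 2, ...) {
  cat(sprintf("Nutritional quality indices for %s\n", x$sample_id))
  lab <- c(ps = "PS (PUFA/SFA)", ia = "IA (atherogenicity)",
           it = "IT (thrombogenicity)", h_over_h = "h/H",
           hpi = "HPI", ui = "UI (unsaturation)",
           sed = "SED (EPA+DHA, %)", tfa = "TFA (trans, %)")
  for (k in names(lab)) {
    v <- x[[k]]
    cat(sprintf("  %-22s %s\n", lab[[k]],
                if (is.na(v)) "undefined" else formatC(round(v, digits),
                                                       format = "f", digits = digits)))
  }
  invisible(x)
}

#' Flatten an index report to a plain list
#'
#' Rounds for display according to `precision` (round-half-even, the default
#' IEEE behaviour of [round()]); pass `precision = NA` to keep full
#' precision.
#'
#' @param r an `fa_index_report`.
#' @param precision decimal places for display rounding, default 2.
#' @return named list of the eight index values plus `sample_id` and
#'   `undefined`.
#' @export
report_as_list <- function(r, precision = 2) {
  stopifnot(inherits(r, "fa_index_report"))
  keys <- c("ps", "ia", "it", "h_over_h", "hpi", "ui", "sed", "tfa")
  vals <- lapply(keys, function(k) {
    v <- r[[k]]
    if (!is.na(precision) && !is.na(v)) round(v, precision) else v
  })
  names(vals) <- keys
  c(list(sample_id = r$sample_id), vals,
    list(undefined = as.list(r$undefined)))
}
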