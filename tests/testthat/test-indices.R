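# groups objects for the two reference strains, shared across blocks
ref_groups <- local({
  ref <- diatom_reference_profiles()
  lapply(ref, aggregate_profile)
})

test_that("single-index values match hand arithmetic on the reference sums", {
  a <- ref_groups$Ano
  r <- ref_groups$Rho
  expect_equal(index_ps(a), 15.54 / 41.75, tolerance = 1e-12)
  expect_equal(index_ia(a), (0 + 4 * 1.72 + 33.02) / 58.25, tolerance = 1e-12)
  expect_equal(index_it(r),
               40.47 / (17.765 + 10.125 + 8.43 + 2.81 / 20.25),
               tolerance = 1e-12)
  expect_equal(index_h_over_h(a), 19.84 / 34.74, tolerance = 1e-12)
  expect_equal(index_hpi(r), 58.59 / 55.14, tolerance = 1e-12)
  # polyene class sums assembled by hand from the Ano column
  expect_equal(index_ui(a),
               42.71 + 2 * 1.10 + 3 * 1.89 + 4 * 10.27 + 5 * 1.33 + 6 * 0.95,
               tolerance = 1e-12)
  expect_equal(index_sed(r), 2.61 + 0.20, tolerance = 1e-12)
  expect_equal(index_tfa(a), 2.26, tolerance = 1e-12)
})

test_that("degenerate sums raise classed undefined-index errors", {
  empty <- aggregate_profile(fa_profile(character(0), numeric(0)))
  expect_error(index_ps(empty), class = "lipidqi_undefined_index_error")
  expect_error(index_ia(empty), class = "lipidqi_undefined_index_error")
  expect_error(index_it(empty), class = "lipidqi_undefined_index_error")
  expect_error(index_h_over_h(empty), class = "lipidqi_undefined_index_error")
  expect_error(index_hpi(empty), class = "lipidqi_undefined_index_error")
  # UI / SED / TFA have no denominator and stay defined
  expect_equal(index_ui(empty), 0)
  expect_equal(index_sed(empty), 0)
  expect_equal(index_tfa(empty), 0)
})

test_that("nutritional_indices flags undefined indices instead of dying", {
  p <- suppressWarnings(fa_profile(character(0), numeric(0), sample_id = "x"))
  rep <- nutritional_indices(p)
  expect_setequal(rep$undefined, c("ps", "ia", "it", "h_over_h", "hpi"))
  expect_true(is.na(rep$ps) && is.na(rep$hpi))
  expect_equal(rep$ui, 0)
  # an all-saturated profile: only UI/SED/TFA and none of the ratios needing
  # unsaturates; h/H denominator is fine but numerator is 0
  sat <- fa_profile(c("C16:0", "C18:0"), c(60, 40))
  rs <- nutritional_indices(sat)
  expect_setequal(rs$undefined, c("ia", "it"))
  expect_equal(rs$ps, 0)
  expect_equal(rs$h_over_h, 0)
  expect_equal(rs$ui, 0)
})

test_that("each index equals the independent oracle on random profiles", {
  keys <- c("ps", "ia", "it", "h_over_h", "hpi", "ui", "sed", "tfa")
  for (seed in 1:200) {
    df <- random_profile_df(seed)
    want <- oracle_indices(df)
    got <- nutritional_indices(profile_from_df(df))
    for (k in keys) {
      if (is.na(want[[k]])) {
        expect_true(is.na(got[[k]]), info = sprintf("seed %d, %s", seed, k))
      } else {
        expect_equal(got[[k]], want[[k]], tolerance = 1e-12,
                     info = sprintf("seed %d, %s", seed, k))
      }
    }
  }
})

test_that("HPI is the reciprocal of IA whenever both are defined", {
  for (seed in 1:50) {
    g <- aggregate_profile(profile_from_df(random_profile_df(seed)))
    ia <- tryCatch(index_ia(g), lipidqi_undefined_index_error = function(e) NA)
    hpi <- tryCatch(index_hpi(g), lipidqi_undefined_index_error = function(e) NA)
    if (!is.na(ia) && !is.na(hpi) && ia > 0) {
      expect_equal(hpi * ia, 1, tolerance = 1e-12)
    }
  }
})

test_that("ratios are scale-invariant; UI, SED, TFA scale linearly", {
  # IT is deliberately absent from the invariant set: its denominator adds
  # the dimensionless n3/n6 ratio to percent-scaled terms, so rescaling the
  # composition changes it (a property of the published formula itself).
  for (seed in c(3, 17, 91)) {
    df <- random_profile_df(seed)
    df2 <- df; df2$pct <- df2$pct * 2.5
    r1 <- nutritional_indices(profile_from_df(df))
    r2 <- nutritional_indices(profile_from_df(df2))
    for (k in c("ps", "ia", "h_over_h", "hpi")) {
      expect_equal(r2[[k]], r1[[k]], tolerance = 1e-12)
    }
    for (k in c("ui", "sed", "tfa")) {
      expect_equal(r2[[k]], 2.5 * r1[[k]], tolerance = 1e-12)
    }
  }
})

test_that("raising an omega-3 PUFA lowers IT and raises PS, UI and SED", {
  base <- random_profile_df(7)
  bump <- base
  bump$pct[bump$code == "C20:5n3"] <- bump$pct[bump$code == "C20:5n3"] + 5
  r0 <- nutritional_indices(profile_from_df(base))
  r1 <- nutritional_indices(profile_from_df(bump))
  expect_lt(r1$it, r0$it)
  expect_gt(r1$ps, r0$ps)
  expect_gt(r1$ui, r0$ui)
  expect_gt(r1$sed, r0$sed)
})

test_that("index reports satisfy their structural invariants", {
  for (seed in 1:25) {
    g <- aggregate_profile(profile_from_df(random_profile_df(seed)))
    rep <- nutritional_indices(g)
    vals <- unlist(rep[c("ps", "ia", "it", "h_over_h", "hpi", "ui", "sed", "tfa")])
    expect_true(all(vals[!is.na(vals)] >= 0))
    expect_lte(rep$sed, g$pufa + 1e-12)
    expect_lte(rep$tfa, g$mufa + g$pufa + 1e-12)
  }
})

test_that("display rounding is round-half-even at the requested precision", {
  ref <- diatom_reference_profiles()
  out <- report_as_list(nutritional_indices(ref$Ano), precision = 2)
  expect_equal(out$ps, 0.37)
  expect_equal(out$ui, 104.01)
  full <- report_as_list(nutritional_indices(ref$Ano), precision = NA)
  expect_equal(full$ps, 15.54 / 41.75, tolerance = 1e-12)
})
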