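# Independent plain-arithmetic oracle for the nutritional indices.
#
# Deliberately avoids every package code path: its own regex split of the
# shorthand codes and direct sums over a (code, pct) data frame. Used for
# the oracle-equivalence property suite.

oracle_fields <- function(code) {
  m <- regmatches(code, regexec("^C([0-9]+):([0-9]+)(n[0-9]+)?([ct])?$", code))[[1]]
  list(db = as.integer(m[3]), omega = m[4], geom = m[5],
       carbons = as.integer(m[2]))
}

oracle_indices <- function(df) {
  # df: columns code, pct
  f <- lapply(df$code, oracle_fields)
  db <- vapply(f, `[[`, integer(1), "db")
  om <- vapply(f, `[[`, character(1), "omega")
  ge <- vapply(f, `[[`, character(1), "geom")
  cb <- vapply(f, `[[`, integer(1), "carbons")
  p <- df$pct
  pick <- function(codes) sum(p[df$code %in% codes])

  sfa <- sum(p[db == 0]); mufa <- sum(p[db == 1]); pufa <- sum(p[db >= 2])
  ufa <- mufa + pufa
  n3 <- sum(p[db >= 2 & om == "n3"]); n6 <- sum(p[db >= 2 & om == "n6"])
  c12 <- pick("C12:0"); c14 <- pick("C14:0"); c16 <- pick("C16:0")
  c18 <- pick("C18:0")
  cis181 <- sum(p[cb == 18 & db == 1 & ge == "c"])
  trans <- sum(p[ge == "t"])
  ui <- sum(vapply(1:6, function(k) k * sum(p[db == k]), numeric(1)))

  list(
    ps = if (sfa > 0) pufa / sfa else NA_real_,
    ia = if (ufa > 0) (c12 + 4 * c14 + c16) / ufa else NA_real_,
    it = if (n6 > 0) (c14 + c16 + c18) /
           (0.5 * mufa + 0.5 * n6 + 3 * n3 + n3 / n6) else NA_real_,
    h_over_h = if (c12 + c14 + c16 > 0) (cis181 + pufa) / (c12 + c14 + c16)
               else NA_real_,
    hpi = if (c12 + 4 * c14 + c16 > 0) ufa / (c12 + 4 * c14 + c16)
          else NA_real_,
    ui = ui,
    sed = pick("C20:5n3") + pick("C22:6n3"),
    tfa = trans)
}

# random profile over the reference species list as a bare data frame;
# used both for the oracle suite and several property tests
random_profile_df <- function(seed) {
  set.seed(seed)
  codes <- default_species_for_tests()
  w <- rgamma(length(codes), shape = 1)
  pct <- 100 * w / sum(w)
  pct[runif(length(codes)) < 0.15] <- 0
  data.frame(code = codes, pct = pct, stringsAsFactors = FALSE)
}

default_species_for_tests <- function() {
  c("C6:0", "C10:0", "C12:0", "C14:0", "C15:0", "C16:0", "C17:0", "C18:0",
    "C22:0", "C24:0",
    "C14:1", "C16:1", "C17:1", "C18:1n9t", "C18:1n9c", "C22:1n9", "C24:1n9",
    "C18:3n6", "C18:2n6c", "C20:4n6", "C20:5n3", "C20:3n6", "C20:2n6",
    "C22:6n3")
}

profile_from_df <- function(df, sample_id = "oracle") {
  suppressWarnings(
    fa_profile(codes = df$code, percentages = df$pct, sample_id = sample_id))
}
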