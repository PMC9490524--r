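# Shared fixtures: the built-in banks and quick record builders.

banks <- load_builtin_instruments()
ghq_bank <- banks$GHQ12
cbi_bank <- banks$CBI

ghq_record <- function(codes, id = "r1", ts = "2022-01-15") {
  if (length(codes) == 1L) codes <- rep(codes, 12)
  response_record("GHQ12", id, setNames(as.list(codes), names(ghq_bank$items)), ts)
}

cbi_record <- function(codes, id = "r1", ts = "2022-01-15") {
  if (length(codes) == 1L) codes <- rep(codes, 19)
  response_record("CBI", id, setNames(as.list(codes), names(cbi_bank$items)), ts)
}

# CBI record from per-dimension target point values (forward-coded points;
# the reverse item's option is chosen so it CONTRIBUTES the given points)
cbi_record_points <- function(personal, work, client, id = "r1",
                              ts = "2022-01-15") {
  pts <- c(rep_len(personal, 6), rep_len(work, 7), rep_len(client, 6))
  items <- cbi_bank$items
  codes <- vapply(seq_along(items), function(i) {
    if (items[[i]]$reverse) pts[[i]] / 25 else (100 - pts[[i]]) / 25
  }, numeric(1))
  cbi_record(as.integer(codes), id = id, ts = ts)
}

random_ghq_record <- function(id = "r") {
  ghq_record(sample(0:3, 12, replace = TRUE), id = id)
}

all_levels <- c("low", "moderate", "high")

# a scored test record with chosen severity, built through the real engines
fixture_record <- function(ghq_codes = 0L, cbi_points = 0,
                           id = "r1", ts = "2022-01-15") {
  make_record(ghq_record(ghq_codes, id = id, ts = ts),
              cbi_record_points(cbi_points, cbi_points, cbi_points,
                                id = id, ts = ts),
              now = ts)
}
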