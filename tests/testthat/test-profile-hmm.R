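test_that("profile construction follows the gap threshold and normalizes simplexes", {
  msa <- stats::setNames(rep("ACDEF", 4), paste0("r", 1:4))
  hmm <- build_profile(msa)
  expect_equal(hmm$M, 5L)
  expect_equal(AA[apply(hmm$match_em, 1, which.max)],
               c("A", "C", "D", "E", "F"))
  # one column 60% gaps with threshold 0.5 becomes an insert column
  msa2 <- stats::setNames(c("AC-EF", "AC-EF", "AC-EF", "ACDEF", "ACDEF"),
                          paste0("r", 1:5))
  hmm2 <- build_profile(msa2, match_gap_threshold = 0.5)
  expect_equal(hmm2$M, 4L)
  expect_equal(hmm2$column_map, c(1L, 2L, 4L, 5L))
  # random MSA: all probability simplexes sum to 1
  set.seed(3)
  msa3 <- stats::setNames(replicate(6, paste(sample(c(AA, "-"), 12, TRUE,
    prob = c(rep(1, 20), 4)), collapse = "")), paste0("r", 1:6))
  hmm3 <- build_profile(msa3)
  expect_lt(max(abs(rowSums(hmm3$match_em) - 1)), 1e-9)
  for (j in 0:hmm3$M) {
    i <- j + 1L
    expect_equal(hmm3$tMM[i] + hmm3$tMI[i] + hmm3$tMD[i], 1, tolerance = 1e-9)
    expect_equal(hmm3$tII[i] + hmm3$tIM[i], 1, tolerance = 1e-9)
    if (j >= 1) expect_equal(hmm3$tDM[i] + hmm3$tDD[i], 1, tolerance = 1e-9)
  }
  expect_error(build_profile(stats::setNames(c("--", "--"), c("a", "b"))),
               "gap-rich")
})

test_that("Viterbi equals brute-force path enumeration on small profiles", {
  cases <- list(
    list(M = 2, q = "AC", seed = 1), list(M = 2, q = "ACDE", seed = 2),
    list(M = 3, q = "AC", seed = 3), list(M = 3, q = "KLMNP", seed = 4),
    list(M = 4, q = "ACDE", seed = 5), list(M = 4, q = "A", seed = 6),
    list(M = 4, q = "WYVWYV", seed = 7), list(M = 3, q = "DDD", seed = 8))
  for (cs in cases) {
    hmm <- random_small_profile(cs$M, seed = cs$seed)
    got <- score_query(hmm, cs$q)
    want <- brute_viterbi_score(hmm, cs$q)
    expect_equal(got, want, tolerance = 1e-9,
                 label = sprintf("M=%d q=%s", cs$M, cs$q))
  }
})

test_that("consensus queries align all-match and outscore shuffles", {
  set.seed(9)
  msa <- stats::setNames(rep(paste(sample(AA, 30, TRUE), collapse = ""), 5),
                         paste0("r", 1:5))
  hmm <- build_profile(msa)
  cons <- paste(profile_consensus(hmm), collapse = "")
  map <- viterbi_align(hmm, cons)
  expect_identical(map$match_to_query, seq_len(hmm$M))
  s_cons <- map$score
  expect_gt(s_cons, 0)
  set.seed(10)
  for (k in 1:20) {
    shuf <- paste(sample(strsplit(cons, "")[[1]]), collapse = "")
    expect_lt(score_query(hmm, shuf), s_cons)
  }
  # deleting one consensus residue yields exactly one delete state
  del <- paste0(substr(cons, 1, 11), substr(cons, 13, 30))
  mapd <- viterbi_align(hmm, del)
  expect_equal(sum(is.na(mapd$match_to_query)), 1L)
  expect_true(is.na(mapd$match_to_query[12]))
})

test_that("alignment maps are mutually consistent and scores deterministic", {
  set.seed(12)
  msa <- stats::setNames(replicate(4, paste(sample(AA, 25, TRUE),
    collapse = "")), paste0("r", 1:4))
  msa[2] <- msa[1]
  hmm <- build_profile(msa)
  q <- paste0("MM", substr(msa[1], 3, 25), "KR")
  map <- viterbi_align(hmm, q)
  # invertibility on aligned residues
  for (j in which(!is.na(map$match_to_query))) {
    expect_equal(map$query_to_match[map$match_to_query[j]], j)
  }
  for (i in which(!is.na(map$query_to_match))) {
    expect_equal(map$match_to_query[map$query_to_match[i]], i)
  }
  # every query residue accounted for exactly once
  expect_equal(sum(!is.na(map$query_to_match)) + sum(!is.na(map$insert_after)) +
                 sum(map$flank), nchar(q))
  expect_identical(score_query(hmm, q), score_query(hmm, q))
  expect_error(viterbi_align(hmm, ""), "empty")
})

test_that("profiles survive a JSON round trip", {
  hmm <- random_small_profile(6, seed = 20)
  f <- tempfile(fileext = ".json")
  write_profile_json(hmm, f)
  h2 <- read_profile_json(f)
  expect_equal(h2$M, hmm$M)
  expect_equal(h2$match_em, hmm$match_em, tolerance = 1e-12)
  q <- "ACDEFG"
  expect_equal(score_query(h2, q), score_query(hmm, q), tolerance = 1e-9)
})

test_that("profile alignment recovers planted motif columns on synthetic families", {
  # clade-stratified seed rows, as the pipeline's profile stage uses
  ok <- unlist(lapply(c(31, 32, 33), function(sd) {
    p <- simulation_params(n_leaves = 40, seq_length = 400, n_clades = 4,
                           seed = sd)
    fam <- simulate_family(params = p)
    set.seed(1)
    seed_ids <- unlist(lapply(split(names(fam$clades), fam$clades),
                              function(ids)
      sort(sample(ids, min(length(ids), max(2L, round(length(ids) * 0.4)))))))
    hmm <- build_profile(fam$msa[seed_ids])
    spec_cols <- match(p$motif_columns, hmm$column_map)
    expect_false(anyNA(spec_cols))
    vapply(seq_along(fam$sequences), function(i) {
      map <- viterbi_align(hmm, fam$sequences[[i]])
      xs <- strsplit(fam$sequences[[i]], "")[[1]]
      pos <- map$match_to_query[spec_cols]
      st <- ifelse(is.na(pos), "-", xs[ifelse(is.na(pos), 1L, pos)])
      paste(st, collapse = "") == fam$truth$motif_states[i]
    }, logical(1))
  }))
  expect_gte(mean(ok), 0.95)
})
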