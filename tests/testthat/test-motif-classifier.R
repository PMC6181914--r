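test_that("motif spec and assignments carry exactly eight anchored positions", {
  spec <- motif_spec()
  expect_length(spec$columns, 8L)
  expect_equal(spec$ecnhaa_residues, c(131L, 132L, 133L, 134L, 159L, 163L,
                                       164L, 300L))
  expect_equal(spec$ecnhaa_aux, 108L)
  expect_equal(spec$segment_means, c(23L, 156L))
  expect_error(motif_spec(columns = 1:7), "8 positions")
  expect_error(motif_spec(columns = c(1:7, 7)), "increasing")
  expect_error(motif_assignment(c("A", "T", "D")), "8 states")
  m <- motif_assignment(c("A", "T", "D", "I", "L", "D", "D", "K"), aux = "P")
  expect_length(m$states, 8L)
})

test_that("family rule implements the E5+R8 fingerprint conservatively", {
  cpa1 <- motif_assignment(c("P", "T", "D", "P", "E", "N", "D", "R"))
  expect_equal(classify_family(cpa1)$family, "CPA1")
  ec <- motif_assignment(c("A", "T", "D", "I", "L", "D", "D", "K"), aux = "P")
  expect_equal(classify_family(ec)$family, "CPA2")
  half <- classify_family(motif_assignment(c("A", "T", "D", "I", "E", "D",
                                             "D", "K")))
  expect_equal(half$family, "ambiguous")
  expect_true("E5_WITHOUT_R8" %in% half$flags)
  gapped <- classify_family(motif_assignment(c("A", "T", "D", "I", "L", "D",
                                               "D", "-")))
  expect_equal(gapped$family, "ambiguous")
  expect_true("GAPPED_MOTIF" %in% gapped$flags)
})

test_that("electrogenicity follows the D6+K8 rule with its documented exceptions", {
  ec <- motif_assignment(c("A", "T", "D", "I", "L", "D", "D", "K"), aux = "P")
  expect_equal(classify_electrogenicity(ec, "CPA2")$electrogenicity,
               "electrogenic")
  # D163N-like motif: asparagine at position 6 abolishes electrogenicity
  d163n <- motif_assignment(c("A", "T", "D", "I", "L", "N", "D", "K"),
                            aux = "E")
  expect_equal(classify_electrogenicity(d163n, "CPA2")$electrogenicity,
               "electroneutral")
  # AtKEA2-like: glutamine at position 6, lysine at 8
  kea <- motif_assignment(c("L", "S", "S", "T", "S", "Q", "D", "K"))
  expect_equal(classify_electrogenicity(kea, "CPA2")$electrogenicity,
               "electroneutral")
  # mammalian NHA-like: two aspartates plus R8 and the TM-3 glutamate
  nha <- motif_assignment(c("A", "T", "D", "I", "T", "D", "D", "R"), aux = "E")
  out <- classify_electrogenicity(nha, classify_family(nha)$family)
  expect_equal(out$electrogenicity, "electroneutral")
  expect_true("NHA_LIKE_E_TM3" %in% out$flags)
  # all CPA1s are electroneutral
  cpa1 <- motif_assignment(c("S", "T", "D", "A", "E", "N", "D", "R"))
  expect_equal(classify_electrogenicity(cpa1, "CPA1")$electrogenicity,
               "electroneutral")
  # non-acidic position 7 flags likely transport deficiency
  dead <- motif_assignment(c("A", "T", "D", "I", "L", "D", "N", "K"))
  expect_true("POS7_NOT_ACIDIC" %in%
                classify_electrogenicity(dead, "CPA2")$flags)
  gap6 <- motif_assignment(c("A", "T", "D", "I", "L", "-", "D", "K"))
  expect_equal(classify_electrogenicity(gap6, "CPA2")$electrogenicity,
               "unknown")
})

test_that("selectivity keys on serine/threonine at positions 1 and 4", {
  expect_equal(classify_selectivity(
    motif_assignment(c("S", "T", "D", "A", "E", "N", "D", "R")))$selectivity, "K")
  expect_equal(classify_selectivity(
    motif_assignment(c("L", "S", "S", "T", "S", "Q", "D", "K")))$selectivity, "K")
  expect_equal(classify_selectivity(
    motif_assignment(c("A", "T", "D", "I", "L", "D", "D", "K")))$selectivity, "Na")
  expect_equal(classify_selectivity(
    motif_assignment(c("P", "T", "D", "P", "E", "N", "D", "R")))$selectivity, "Na")
  # polar-but-not-ST anchor is unknown
  expect_equal(classify_selectivity(
    motif_assignment(c("N", "T", "D", "I", "L", "D", "D", "K")))$selectivity,
    "unknown")
  expect_equal(classify_selectivity(
    motif_assignment(c("-", "T", "D", "-", "L", "D", "D", "K")))$selectivity,
    "unknown")
})

test_that("the classifier is total and CPA1 implies electroneutral over rule space", {
  s1s <- c("S", "A", "N", "-")
  s5s <- c("E", "L", "-")
  s6s <- c("D", "Q", "-")
  s7s <- c("D", "N")
  s8s <- c("R", "K", "H", "Q", "-")
  auxs <- c("E", "P")
  for (s1 in s1s) for (s5 in s5s) for (s6 in s6s) for (s7 in s7s)
    for (s8 in s8s) for (aux in auxs) {
      m <- motif_assignment(c(s1, "T", "D", "I", s5, s6, s7, s8), aux = aux)
      fam <- classify_family(m)
      el <- classify_electrogenicity(m, fam$family)
      sel <- classify_selectivity(m, fam$family)
      expect_true(fam$family %in% c("CPA1", "CPA2", "ambiguous"))
      expect_true(el$electrogenicity %in% c("electrogenic", "electroneutral",
                                            "unknown"))
      expect_true(sel$selectivity %in% c("Na", "K", "unknown"))
      if (fam$family == "CPA1")
        expect_equal(el$electrogenicity, "electroneutral")
    }
})

test_that("clade assignment is nearest-consensus with margins and tie flags", {
  ref <- load_clade_reference()
  for (i in seq_len(nrow(ref))) {
    m <- motif_assignment(strsplit(ref$motif[i], "")[[1]], aux = ref$aux[i])
    out <- assign_clade(m, ref)
    expect_equal(out$clade, ref$clade[i])
    expect_gt(out$margin, 0)
  }
  # equidistant query raises the tie flag and resolves lexicographically
  two <- ref[ref$clade %in% c("NapA-I", "NapA-II"), ]
  a <- strsplit(two$motif[1], "")[[1]]
  b <- strsplit(two$motif[2], "")[[1]]
  diffs <- which(a != b)
  q <- a; q[diffs[1]] <- b[diffs[1]]
  # make the query differ from both by swapping a balanced number of states
  if (length(diffs) %% 2 == 1) q[1] <- "Y"
  d_a <- sum(a != q); d_b <- sum(b != q)
  if (d_a == d_b) {
    out <- assign_clade(motif_assignment(q), two)
    expect_true("AMBIGUOUS_CLADE" %in% out$flags)
    expect_equal(out$clade, sort(two$clade)[1])
  }
  expect_error(assign_clade(motif_assignment(a), ref[0, ]), "reference")
})

test_that("extract_motif reads anchors from a self-alignment with EcNhaA numbering", {
  # synthetic EcNhaA-like sequence: random background with the reference
  # motif states planted at the EcNhaA residue numbers
  set.seed(77)
  seq <- sample(AA, 400, TRUE)
  seq[c(131, 132, 133, 134, 159, 163, 164, 300)] <-
    c("A", "T", "D", "I", "L", "D", "D", "K")
  seq[108] <- "P"
  qs <- paste(seq, collapse = "")
  msa <- stats::setNames(rep(qs, 4), paste0("r", 1:4))
  hmm <- build_profile(msa)
  map <- viterbi_align(hmm, qs)
  m <- extract_motif(map, qs, motif_spec())
  expect_equal(m$states, c("A", "T", "D", "I", "L", "D", "D", "K"))
  expect_equal(m$query_pos, c(131L, 132L, 133L, 134L, 159L, 163L, 164L, 300L))
  expect_equal(m$aux, "P")
  expect_equal(m$aux_pos, 108L)
  # deletion spanning the position-8 anchor leaves a gap state
  q_del <- paste(seq[-(295:305)], collapse = "")
  m2 <- extract_motif(viterbi_align(hmm, q_del), q_del, motif_spec())
  expect_equal(m2$states[8], "-")
  expect_error(extract_motif(map, qs, motif_spec(columns = c(1:7, 500))),
               "profile")
})

test_that("full classification composes the stages and fails coverage gracefully", {
  p <- simulation_params(n_leaves = 24, seq_length = 150, n_clades = 4,
                         seed = 91)
  fam <- simulate_family(params = p)
  hmm <- build_profile(fam$msa)
  spec <- motif_spec(columns = match(p$motif_columns, hmm$column_map),
                     aux_column = match(p$aux_column, hmm$column_map))
  res <- lapply(fam$sequences, classify, hmm = hmm, spec = spec)
  tab <- classification_table(res)
  expect_identical(tab$family, fam$truth$family)
  expect_identical(tab$electrogenicity, fam$truth$electrogenicity)
  expect_identical(tab$selectivity, fam$truth$selectivity)
  # determinism: byte-identical result tables
  tab2 <- classification_table(lapply(fam$sequences, classify, hmm = hmm,
                                      spec = spec))
  expect_identical(tab, tab2)
  # a non-homologous random query fails the coverage screen
  set.seed(5)
  junk <- paste(sample(AA, 30, TRUE), collapse = "")
  out <- classify(junk, hmm, spec)
  expect_true("COVERAGE_FAIL" %in% out$flags)
  expect_equal(out$family, "ambiguous")
})
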