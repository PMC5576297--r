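test_that("closed forms hold on uniform windows", {
  for (w in c(3L, 5L, 13L)) {
    c0 <- 0.5
    inst <- uniform_instance(w, c0)
    cons <- encode_conservation(inst)
    expect_length(cons, 20L * w)
    expect_true(all(cons == c0))

    pair <- encode_pair_relationships(inst)
    expect_length(pair, 400L)
    expect_equal(unname(pair), rep((w - 1) * c0^2, 400L), tolerance = 1e-12)

    multi <- encode_multi_relationships(inst)
    expect_equal(unname(multi$left), rep((w + 1) / 2 * c0, 20L),
                 tolerance = 1e-12)
    expect_equal(unname(multi$right), rep((w + 1) / 2 * c0, 20L),
                 tolerance = 1e-12)
  }
})

test_that("pair block matches the brute-force triple-loop oracle", {
  k <- 0L
  for (w in seq(3L, 15L, 2L)) {
    for (rep in 1:15) {
      k <- k + 1L
      inst <- random_instance(w, seed = 1000L + k)
      expect_equal(unname(encode_pair_relationships(inst)),
                   unname(pair_oracle(inst)), tolerance = 1e-9)
    }
  }
  expect_gte(k, 100L)
})

test_that("a hand-computed 3-window pair entry is reproduced", {
  inst <- uniform_instance(3L, 0)
  inst$window[2L, "C"] <- 0.8           # target row
  inst$window[1L, "A"] <- 0.6           # context rows
  inst$window[3L, "A"] <- 0.4
  pair <- encode_pair_relationships(inst)
  expect_equal(unname(pair["pair_A_C"]), 0.8 * (0.6 + 0.4), tolerance = 1e-12)
})

test_that("fully padded context yields an all-zero pair block", {
  g <- normalize_pssm(gen_pssm(1L, seed = 9L))
  inst <- extract_window(g, 1L, 3L)
  expect_true(all(encode_pair_relationships(inst) == 0))
})

test_that("reversing the window fixes the pair block and swaps multi blocks", {
  for (s in 1:5) {
    inst <- random_instance(9L, seed = 300L + s)
    rev_inst <- inst
    rev_inst$window <- inst$window[inst$window_size:1L, , drop = FALSE]
    rev_inst$pad_mask <- rev(inst$pad_mask)
    expect_equal(encode_pair_relationships(inst),
                 encode_pair_relationships(rev_inst), tolerance = 1e-12)
    m <- encode_multi_relationships(inst)
    mr <- encode_multi_relationships(rev_inst)
    expect_equal(unname(m$left), unname(mr$right), tolerance = 1e-12)
    expect_equal(unname(m$right), unname(mr$left), tolerance = 1e-12)
  }
})

test_that("multi blocks include the target row and respect padding", {
  g <- normalize_pssm(gen_pssm(6L, seed = 5L))
  inst <- extract_window(g, 1L, 5L)      # left flank fully padded
  m <- encode_multi_relationships(inst)
  expect_equal(unname(m$left), unname(g$values[1L, ]), tolerance = 1e-12)
})

test_that("PSSM-RT dimension formula 20w + 440 holds", {
  for (w in seq(3L, 15L, 2L)) {
    v <- assemble_pssm_rt(uniform_instance(w, 0.3))
    expect_length(v, 20L * w + 440L)
    schema <- attr(v, "schema")
    expect_equal(schema$length, c(20L * w, 400L, 20L, 20L))
    expect_equal(sum(schema$length), length(v))
  }
  expect_length(assemble_pssm_rt(uniform_instance(13L, 0.1)), 700L)
  expect_length(assemble_pssm_rt(uniform_instance(3L, 0.1)), 500L)
})

test_that("pair and multi entries respect their theoretical bounds", {
  for (s in 1:10) {
    w <- sample(seq(3L, 15L, 2L), 1L)
    inst <- random_instance(w, seed = 700L + s)
    pair <- encode_pair_relationships(inst)
    multi <- encode_multi_relationships(inst)
    expect_true(all(pair >= 0 & pair <= w - 1))
    expect_true(all(multi$left >= 0 & multi$left <= (w + 1) / 2))
    expect_true(all(multi$right >= 0 & multi$right <= (w + 1) / 2))
    expect_true(all(encode_conservation(inst) >= 0 &
                      encode_conservation(inst) <= 1))
  }
})

test_that("sequence features encode composition, identity and tracks", {
  chain <- protein_chain("s_A", "AAAAA")
  g <- normalize_pssm(gen_pssm(5L, seed = 1L, sequence = "AAAAA"))
  inst <- extract_window(g, 3L, 3L, chain)
  v <- encode_sequence_features(inst, warn = FALSE)
  expect_equal(unname(v["comp_A"]), 1)
  expect_equal(sum(v[paste0("comp_", PSSM_COLUMNS)]), 1)
  expect_equal(unname(v["id_A"]), 1)
  expect_equal(sum(v[paste0("id_", PSSM_COLUMNS)]), 1)
  expect_true(all(v[grep("^(ss|acc)_", names(v))] == 0))
  missing_track_warnings <- capture_warnings(encode_sequence_features(inst))
  expect_match(missing_track_warnings, "secondary-structure", all = FALSE)
  expect_match(missing_track_warnings, "accessibility", all = FALSE)

  chain_r <- protein_chain("s_B", "ARRRA")
  g2 <- normalize_pssm(gen_pssm(5L, seed = 2L, sequence = "ARRRA"))
  inst_r <- extract_window(g2, 3L, 3L, chain_r)
  ss <- c("C", "H", "H", "H", "C")
  acc <- c(0.1, 0.2, 0.3, 0.4, 0.5)
  v2 <- encode_sequence_features(inst_r, ss, acc, chain_length = 5L,
                                 warn = FALSE)
  expect_equal(unname(v2["id_R"]), 1)
  expect_equal(unname(v2["ss_0_H"]), 1)
  expect_equal(unname(v2["ss_0_E"]), 0)
  expect_equal(unname(v2["acc_0"]), 0.3)
  expect_equal(unname(v2["acc_-1"]), 0.2)
  expect_error(encode_sequence_features(inst_r, ss[1:3], chain_length = 5L),
               "length")
})

test_that("physicochemical block scales, repeats and zero-pads correctly", {
  tab <- aa_property_table()
  expect_equal(dim(tab$raw), c(20L, 8L))
  expect_true(all(tab$scaled >= 0 & tab$scaled <= 1))

  chain <- protein_chain("p_A", "GGG")
  g <- normalize_pssm(gen_pssm(3L, seed = 1L, sequence = "GGG"))
  inst <- extract_window(g, 2L, 3L, chain)
  v <- encode_physicochemical(inst, tab)
  expect_length(v, 24L)
  expect_equal(unname(v[1:8]), unname(v[9:16]))
  expect_equal(unname(v[1:8]), unname(tab$scaled["G", ]))

  # W has the largest molecular mass -> scaled mass exactly 1
  expect_equal(unname(tab$scaled["W", "mass"]), 1)

  edge <- extract_window(g, 1L, 3L, chain)
  ve <- encode_physicochemical(edge, tab)
  expect_true(all(ve[1:8] == 0))
})

test_that("a property table missing an amino acid is rejected", {
  tmp <- tempfile(fileext = ".tsv")
  full <- utils::read.delim(system.file("extdata", "aa_properties.tsv",
                                        package = "pssmrt"),
                            comment.char = "#")
  utils::write.table(full[full$aa != "W", ], tmp, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  expect_error(aa_property_table(tmp), "W")
})

test_that("encode_chains aligns instances with meta and feature TSV export", {
  ds <- small_dataset(seed = 11L, n_chains = 2L)
  enc <- encode_chains(ds$chains, normalize_all(ds$pssms), w = 5L)
  total <- sum(vapply(ds$chains, `[[`, 0L, "length"))
  expect_equal(nrow(enc$meta), total)
  expect_equal(nrow(enc$pssm_rt), total)
  expect_equal(ncol(enc$pssm_rt), 20L * 5L + 440L)
  expect_equal(ncol(enc$sequence), 20L + 3L * 5L + 5L + 20L)
  expect_equal(ncol(enc$physicochemical), 8L * 5L)

  f <- tempfile(fileext = ".tsv")
  write_feature_tsv(enc, "pssm_rt", f)
  back <- utils::read.delim(f, check.names = FALSE)
  expect_equal(nrow(back), total)
  expect_equal(back$pair_A_A, unname(enc$pssm_rt[, "pair_A_A"]))
})

test_that("ss2 and accessibility readers parse their formats", {
  ss2 <- c("# PSIPRED VFORMAT (PSIPRED V4.0)", "",
           "   1 M C   0.997  0.002  0.001",
           "   2 K H   0.100  0.850  0.050",
           "   3 V E   0.050  0.100  0.850")
  f <- tempfile(fileext = ".ss2")
  writeLines(ss2, f)
  r <- read_ss2(f)
  expect_equal(r$states, c("C", "H", "E"))
  expect_equal(unname(r$probs[2L, "H"]), 0.85)

  fa <- tempfile()
  writeLines(c("1 0.35", "2 0.72", "3 0.10"), fa)
  expect_equal(read_sable(fa), c(0.35, 0.72, 0.10))

  fb <- tempfile()
  writeLines(c("ACC", "930"), fb)
  expect_equal(read_sable(fb), c(9, 3, 0) / 9)
})
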