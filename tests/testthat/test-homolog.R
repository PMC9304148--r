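test_that("planted Wx9EH motif is found at the exact position", {
  seq <- paste0("AAA", "W", strrep("G", 9), "EH", "AAA")
  hits <- find_motif(seq, carh_motifs()$Wx9EH)
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$start, 4L)
  expect_identical(hits$end, 15L)
  expect_identical(hits$matched_span, paste0("W", strrep("G", 9), "EH"))
})

test_that("a Trp-less sequence with EH does not match Wx9EH", {
  # the CarA situation: B12 motif and the EH retained, Trp lost
  seq <- paste0(strrep("A", 10), "EH", strrep("A", 10))
  expect_false(grepl("W", seq, fixed = TRUE))
  hits <- find_motif(seq, carh_motifs()$Wx9EH)
  expect_identical(nrow(hits), 0L)
})

test_that("motif matcher agrees with the exhaustive sliding-window oracle", {
  motifs <- carh_motifs()
  withr::with_seed(42, {
    for (rep in 1:200) {
      n <- sample(60:140, 1L)
      seq <- random_protein_str(n)
      # enrich with partial motif fragments so matches actually occur
      if (rep %% 3L == 0L)
        seq <- paste0(substr(seq, 1, 20), "W", random_protein_str(9), "EH",
                      substr(seq, 33, n))
      if (rep %% 5L == 0L)
        seq <- paste0(substr(seq, 1, 10), "R", random_protein_str(1), "WERRY",
                      substr(seq, 18, n))
      for (m in motifs) {
        got <- find_motif(seq, m)
        want <- oracle_find_motif(seq, m)
        expect_identical(got$start, want$start)
        expect_identical(got$end, want$end)
      }
    }
  })
})

test_that("X never satisfies a fixed residue but passes through spacers", {
  spec <- carh_motifs()$Wx9EH
  expect_identical(nrow(find_motif(paste0("X", strrep("A", 9), "EH"), spec)), 0L)
  hit <- find_motif(paste0("W", "XXXXXXXXX", "EH"), spec)
  expect_identical(nrow(hit), 1L)
})

test_that("classification follows the motif co-occurrence criterion", {
  carh <- gen_protein("CarH", seed = 5)
  expect_identical(classify_homolog(carh$sequence)$label, "CarH")

  # mutating the Trp of Wx9EH turns a CarH call into CarA
  seq <- carh$sequence
  w_at <- carh$truth$wx9eh[1]
  expect_identical(substr(seq, w_at, w_at), "W")
  substr(seq, w_at, w_at) <- "A"
  call <- classify_homolog(seq)
  expect_identical(call$label, "CarA")
  expect_true(call$evidence[["B12_binding"]])
  expect_false(call$evidence[["Wx9EH"]])

  withr::with_seed(9, {
    plain <- random_protein_str(300)
  })
  expect_identical(classify_homolog(plain)$label, "non_member")
})

test_that("length filter flags but does not relabel", {
  carh <- gen_protein("CarH", seed = 6)
  long <- paste0(carh$sequence, strrep("A", 60))
  call <- classify_homolog(long)
  expect_identical(call$label, "CarH")
  expect_false(call$passed_filters)
})

test_that("labels are invariant to mutations outside motif spans", {
  carh <- gen_protein("CarH", seed = 7)
  truth <- carh$truth
  motif_pos <- c(truth$rxwerry[1]:truth$rxwerry[2],
                 truth$wx9eh[1]:truth$wx9eh[2],
                 truth$b12[1]:truth$b12[2])
  withr::with_seed(13, {
    for (rep in 1:25) {
      seq <- carh$sequence
      free <- setdiff(seq_len(nchar(seq)), motif_pos)
      at <- sample(free, 5L)
      for (i in at) substr(seq, i, i) <- sample(c("A", "L", "K", "Q"), 1L)
      expect_identical(classify_homolog(seq)$label, "CarH")
    }
  })
})

test_that("widening B12 spacer bounds only adds hits (monotonicity)", {
  narrow <- carh_motifs()$B12_binding
  wide <- motif_spec("B12_binding", local({
    els <- narrow$elements
    els[[10]] <- list(min = 20L, max = 30L)  # the x22-27 spacer
    els
  }))
  withr::with_seed(21, {
    for (rep in 1:20) {
      prot <- gen_protein(sample(c("CarH", "CarA"), 1L), seed = rep)
      h_narrow <- find_motif(prot$sequence, narrow)
      h_wide <- find_motif(prot$sequence, wide)
      key <- function(h) paste(h$start, h$end)
      expect_true(all(key(h_narrow) %in% key(h_wide)))
    }
  })
})

test_that("domain split places the B12 motif inside the CBD", {
  hits <- data.frame(motif = "RxWERRY", start = 40L, end = 46L,
                     matched_span = "RAWERRY")
  sp <- split_domains(strrep("A", 300), hits)
  expect_identical(sp$dbd_end, 76L)
  expect_identical(sp$cbd_start, 77L)

  expect_warning(
    sp2 <- split_domains(strrep("A", 60),
                         data.frame(motif = "RxWERRY", start = 40L, end = 46L,
                                    matched_span = "RAWERRY")),
    "capped")
  expect_lt(sp2$dbd_end, 60L)

  expect_error(split_domains("AAAA", data.frame(motif = character(),
                                                start = integer(),
                                                end = integer())),
               "RxWERRY")

  carh <- gen_protein("CarH", seed = 8)
  call <- classify_homolog(carh$sequence)
  sp3 <- split_domains(carh$sequence, call$hits)
  b12 <- call$hits[call$hits$motif == "B12_binding", ][1, ]
  expect_gte(b12$start, sp3$cbd_start)
})

test_that("pairwise identity is symmetric, bounded and exact on anchors", {
  a <- "MKTAYIAKQR"
  expect_equal(pairwise_identity(a, a), 100)
  expect_equal(pairwise_identity("AAAA", "GGGG"), 0)
  b <- "MKTAYIGKQR"
  expect_equal(pairwise_identity(a, b), pairwise_identity(b, a))
  expect_true(pairwise_identity(a, b) >= 0 && pairwise_identity(a, b) <= 100)
  expect_error(pairwise_identity("", a), "empty")
})

test_that("global alignment matches the independent Gotoh oracle", {
  pairs <- list(
    c("MKTAYIAKQR", "MKTAYIAKQR"),   # identical
    c("MKTAYIAKQR", "MKTAYIGKQR"),   # single substitution
    c("MKTAYIAKQR", "MKTAYAKQR"),    # single deletion
    c("WERRYWERRY", "WERRYAWERRY"),  # insertion between blocks
    c("MKTAYI", "MKTAYIAKQR")        # terminal extension
  )
  for (pr in pairs) {
    want <- oracle_global_align(pr[1], pr[2])
    got_score <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(pr[1]), Biostrings::AAString(pr[2]),
      type = "global", substitutionMatrix = "BLOSUM62",
      gapOpening = 10, gapExtension = 0.5, scoreOnly = TRUE)
    expect_equal(got_score, want$score, tolerance = 1e-9)
    expect_equal(pairwise_identity(pr[1], pr[2]), want$identity,
                 tolerance = 1e-9)
  }
})

test_that("identity matrix has a 100 diagonal and matches per-pair calls", {
  withr::with_seed(31, {
    prots <- c(p1 = gen_protein("CarH", seed = 1)$sequence,
               p2 = gen_protein("CarA", seed = 2)$sequence,
               p3 = gen_protein("CarH", seed = 3)$sequence)
  })
  refs <- prots[1:2]
  m <- identity_matrix(prots, refs)
  expect_true(all(m$whole >= 0 & m$whole <= 100))
  expect_equal(m$whole[m$query == "p1" & m$reference == "p1"], 100)
  for (i in seq_len(nrow(m))) {
    expect_equal(m$whole[i],
                 pairwise_identity(prots[[m$query[i]]], refs[[m$reference[i]]]))
  }
  # reproducible run to run
  m2 <- identity_matrix(prots, refs)
  expect_identical(m, m2)
})
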