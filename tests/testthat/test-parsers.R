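test_that("RR contact files parse in both dialects with headers", {
  m5 <- read_rr("1 9 0 8 0.95\n2 11 0 8 0.80\n")
  expect_equal(nrow(m5), 2)
  expect_equal(m5$score, c(0.95, 0.80))

  m3 <- read_rr("PFRMAT RR\nMODEL 1\n1 9 0.95\nEND\n")
  expect_equal(nrow(m3), 1)
  expect_equal(m3$score, 0.95)

  mixed <- read_rr("PFRMAT RR\n1 9 0.9\n2 11 0 8 0.8\n")
  expect_equal(nrow(mixed), 2)

  expect_error(read_rr("1 9 x\n"), "line 1.*'x'")
  expect_error(read_rr("PFRMAT RR\nEND\n"), "no contacts found")
  expect_error(read_rr("1 9 0.5\n", seq_length = 5), "exceeds sequence length")
})

test_that("RR parsing accounts for every input line", {
  text <- "PFRMAT RR\nTARGET T1\nMALWMRLLPL\n\n1 9 0.9\n2 8 0.5\nEND\n"
  m <- read_rr(text)
  stats <- attr(m, "parse_stats")
  expect_equal(sum(stats), length(strsplit(text, "\n")[[1]]))
  expect_equal(unname(stats["data"]), 2L)
  expect_equal(map_length(m), 10L)  # from embedded sequence
  expect_equal(map_sequence(m), "MALWMRLLPL")
})

test_that("RR round-trips preserve maps exactly in both dialects", {
  set.seed(42)
  for (rep in 1:25) {
    m <- random_contact_map(L = sample(20:80, 1), n = sample(1:40, 1))
    m <- contact_map(tibble::as_tibble(m),
                     sequence = paste(sample(LETTERS[1:20], map_length(m),
                                             replace = TRUE), collapse = ""))
    for (dialect in c("5col", "3col")) {
      back <- read_rr(write_rr(m, dialect = dialect))
      expect_identical(map_tbl(back), map_tbl(m))
      expect_identical(map_length(back), map_length(m))
    }
  }
})

test_that("RMODE 2 distograms renormalize small drifts and reject arity errors", {
  hdr <- "PFRMAT RR\nRMODE 2\n"
  d <- read_rr_distogram(paste0(hdr, "1 9 1 0 0 0 0 0 0 0 0 0\n"))
  expect_equal(d$probs[[1]][1], 1)

  drift <- paste0(hdr, "1 9 0.505 0.5 0 0 0 0 0 0 0 0\n")
  d2 <- read_rr_distogram(drift)
  expect_equal(sum(d2$probs[[1]]), 1, tolerance = 1e-12)

  expect_error(read_rr_distogram(paste0(hdr, "1 9 1 0 0 0 0 0 0 0 0\n")),
               "9 probabilities for 10")
  expect_error(read_rr_distogram(paste0(hdr, "1 9 0.9 0.2 0 0 0 0 0 0 0 0\n")),
               "sums to 1.1")
  expect_error(read_rr_distogram("1 9 1 0 0 0 0 0 0 0 0 0\n"),
               "RMODE 2")
  expect_s3_class(read_rr_distogram("1 9 1 0 0 0 0 0 0 0 0 0\n", force = TRUE),
                  "distogram")
})

test_that("PSIPRED ss2 parsing maps states and called-state probabilities", {
  body <- "# PSIPRED VFORMAT\n\n1 M C 0.9 0.1 0.0\n2 A H 0.1 0.8 0.1\n3 L H 0.1 0.9 0.0\n"
  t <- read_psipred_ss2(body)
  expect_equal(t$state, c("C", "H", "H"))
  expect_equal(t$value, c(0.9, 0.8, 0.9))
  expect_equal(unname(track_palette(t)[c("H", "C")]), c("red", "green"))

  expect_error(read_psipred_ss2("# header only\n"), "no residues")
  expect_error(read_psipred_ss2("1 M X 0.9 0.1 0.0\n"), "unknown.*'X'")
  expect_error(read_psipred_ss2("1 M C 0.9 0.1 0.0\n3 A H 0.1 0.8 0.1\n"),
               "gap in residue numbering")
})

test_that("IUPred disorder parsing thresholds at 0.5, boundary disordered", {
  t <- read_iupred("1 M 0.2\n2 A 0.7\n")
  expect_equal(t$state, c("ordered", "disordered"))
  expect_equal(t$value, c(0.2, 0.7))
  expect_equal(read_iupred("1 M 0.5\n")$state, "disordered")
  expect_error(read_iupred("1 M 1.3\n"), "outside \\[0, 1\\]")
})

test_that("TOPCONS topology strings map the i/o/M/S alphabet", {
  t <- read_topcons("ooMMMiii")
  expect_equal(nrow(t), 8)
  expect_equal(t$state[3:5], rep("membrane", 3))
  expect_equal(t$state[1:2], rep("outside", 2))
  runs <- track_runs(t)
  expect_equal(nrow(runs), 3)

  expect_error(read_topcons(""), "empty topology")
  expect_error(read_topcons("ooXii"), "'X' at position 3")

  full <- paste("TOPCONS result file",
                "TOPCONS predicted topology:", "ooMMM", "iii", "",
                "OCTOPUS predicted topology:", "ooooo", sep = "\n")
  t2 <- read_topcons(full)
  expect_equal(t2$state, t$state)
})

test_that("ConSurf grades parse 1-9 with gradient endpoints", {
  t <- read_consurf("1 M 1\n2 A 9\n")
  pal <- track_palette(t)
  expect_equal(unname(pal["1"]), "#F7FBFF")
  expect_equal(unname(pal["9"]), "#08306B")
  expect_equal(t$value, c(1, 9))

  expect_error(read_consurf("1 M 0\n"), "outside 1-9")
  expect_equal(nrow(read_consurf("1 1\n2 5\n3 9\n4 4\n5 2\n")), 5)
  # header rows with non-integer first field are skipped
  expect_equal(nrow(read_consurf("POS SEQ GRADE\n1 M 3\n")), 1)
})

test_that("custom-track instructions parse and later lines win on overlap", {
  ins <- read_custom_track("16 42 purple loop1\n105 131 purple loop2\n")
  expect_equal(nrow(ins), 2)
  expect_equal(ins$start, c(16L, 105L))
  expect_equal(ins$end, c(42L, 131L))
  expect_equal(ins$colour, c("purple", "purple"))

  expect_error(read_custom_track("5 3 red\n"), "start after end")
  expect_equal(nrow(read_custom_track("# comment only\n")), 0)
  expect_error(read_custom_track("1 5 notacolour\n"), "unparseable colour")
  expect_error(read_custom_track("1 5 red lbl 7\n"), "outside \\[-4, 4\\]")

  over <- read_custom_track("1 10 red a\n5 8 blue b\n")
  t <- track_from_instructions(over, 12)
  expect_equal(t$state[5:8], rep("b", 4))
  expect_equal(t$state[c(1, 4, 9, 10)], rep("a", 4))
  expect_equal(t$state[11:12], rep("none", 2))

  hinted <- read_custom_track("1 4 red a 3\n6 9 blue b 4\n")
  t3 <- track_from_instructions(hinted, 10, slot = 3)
  expect_equal(sum(t3$state == "a"), 4)
  expect_equal(sum(t3$state == "b"), 0)
})

test_that("FASTA reading is single-record, whitespace-tolerant", {
  r <- read_fasta(">x\nMALW\n")
  expect_equal(r$length, 4)
  expect_equal(r$sequence, "MALW")
  expect_equal(r$id, "x")
  expect_error(read_fasta(">a\nM\n>b\nA\n"), "multi-record")
  expect_equal(read_fasta(">x\nma lw\n")$sequence, "MALW")
  expect_warning(read_fasta(">x\nMA1W\n"), "non-amino-acid")
})
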