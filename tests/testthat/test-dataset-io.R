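test_that("in-house dialect rows map to records, pairs split on comma", {
  path <- write_inhouse_csv(data.frame(
    pdb_id = c("3OTJ", "3OTJ", "1CBW"),
    chain = "I",
    mutation = c("K15A", "K15A,R17D", "G12V"),
    ddg = c(2.10, 3.5, -0.4),
    stringsAsFactors = FALSE))
  recs <- parse_mutation_table(path, dialect = "inhouse_like", quiet = TRUE)
  expect_length(recs, 3L)
  expect_equal(recs[[1]]$pdb_id, "3OTJ")
  expect_equal(recs[[1]]$ddg_exp, 2.10)
  m <- recs[[1]]$mutations[[1]]
  expect_equal(m[c("chain_id", "position", "wt_aa", "mut_aa")],
               list(chain_id = "I", position = "15", wt_aa = "K", mut_aa = "A"))
  expect_length(recs[[2]]$mutations, 2L)
  expect_equal(recs[[2]]$mutations[[2]]$mut_aa, "D")
  expect_equal(recs[[1]]$source, "inhouse")
})

test_that("malformed rows are rejected individually with reasons", {
  path <- write_inhouse_csv(data.frame(
    pdb_id = "3OTJ", chain = "I",
    mutation = c("K15K", "K15A", "B15A", "K15A,K15D", "???"),
    ddg = 1.0, stringsAsFactors = FALSE))
  recs <- parse_mutation_table(path, dialect = "inhouse_like", quiet = TRUE)
  expect_length(recs, 1L)   # only K15A survives
  rej <- attr(recs, "rejections")
  expect_equal(rej$line, c(1L, 3L, 4L, 5L))
  expect_match(rej$reason[1], "identical")
  expect_match(rej$reason[2], "unknown wild-type")
  expect_match(rej$reason[3], "share a site")
})

test_that("skempi dialect parses embedded chains, pairs and insertion codes", {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(
    pdb = c("3OTJ_E_I", "1REW_AB_C"),
    mutations = c("KI15A", "TC100AL;EC101D"),
    ddg = c(2.1, 0.7), ddg_error = c(0.2, NA),
    stringsAsFactors = FALSE), path, row.names = FALSE)
  recs <- parse_mutation_table(path, dialect = "skempi_like", quiet = TRUE)
  expect_length(recs, 2L)
  expect_equal(recs[[1]]$mutations[[1]]$chain_id, "I")
  expect_equal(recs[[1]]$partner_chains, "E_I")
  expect_equal(recs[[1]]$source, "skempi")
  expect_equal(recs[[1]]$ddg_error, 0.2)
  # insertion code "100A" survives as an opaque position string
  expect_equal(recs[[2]]$mutations[[1]]$position, "100A")
  expect_equal(recs[[2]]$mutations[[1]]$mut_aa, "L")
  expect_equal(recs[[2]]$mutations[[2]]$position, "101")
})

test_that("normalized table round-trips through write/read", {
  specs <- list(
    mutation_record("3OTJ", mutation_spec("I", "15", "K", "A"), 2.1,
                    ddg_error = 0.3),
    mutation_record("1CBW", list(mutation_spec("I", "15", "K", "A"),
                                 mutation_spec("I", "17A", "R", "D")), -1.2,
                    source = "skempi"))
  path <- tempfile(fileext = ".csv")
  write_mutation_table(specs, path)
  back <- read_mutation_table(path)
  expect_equal(back, specs)
  # and a second round trip is byte-stable
  path2 <- tempfile(fileext = ".csv")
  write_mutation_table(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("duplicate resolution prefers in-house and means within-source", {
  inh <- list(mutation_record("3OTJ", mutation_spec("I", "15", "K", "A"), 1.0))
  ske <- list(mutation_record("3OTJ", mutation_spec("I", "15", "K", "A"), 3.0,
                              source = "skempi"))
  merged <- resolve_duplicates(inh, ske)
  expect_length(merged, 1L)
  expect_equal(merged[[1]]$ddg_exp, 1.0)
  expect_equal(merged[[1]]$source, "inhouse")

  # disjoint keys: plain union
  inh5 <- lapply(1:5, function(i)
    mutation_record("3OTJ", mutation_spec("I", as.character(i), "K", "A"), i))
  ske7 <- lapply(1:7, function(i)
    mutation_record("1CBW", mutation_spec("I", as.character(i), "K", "A"), i,
                    source = "skempi"))
  expect_length(resolve_duplicates(inh5, ske7), 12L)

  # within-source duplicates collapse to the mean
  dup <- list(
    mutation_record("3OTJ", mutation_spec("I", "15", "K", "A"), 1.0),
    mutation_record("3OTJ", mutation_spec("I", "15", "K", "A"), 3.0))
  expect_equal(resolve_duplicates(dup, list())[[1]]$ddg_exp, 2.0)
})

test_that("duplicate resolution is idempotent", {
  inh <- lapply(1:4, function(i)
    mutation_record("3OTJ", mutation_spec("I", as.character(i), "K", "A"),
                    i / 2))
  ske <- lapply(3:8, function(i)
    mutation_record("3OTJ", mutation_spec("I", as.character(i), "K", "A"),
                    i, source = "skempi"))
  once <- resolve_duplicates(inh, ske)
  expect_equal(resolve_duplicates(once, list()), once)
  expect_equal(resolve_duplicates(once, ske), once)
})

test_that("toy complexes load with correct chain sequences", {
  toy <- make_toy_complex(5, 4, seed = 1)
  s <- load_toy_complex(toy)
  expect_length(s$partner_a, 1L)
  expect_equal(nchar(s$partner_a[[1]]$sequence), 5L)
  expect_equal(nchar(s$partner_b[[1]]$sequence), 4L)
  expect_equal(s$partner_a[[1]]$sequence, toy$sequence_a)
  expect_equal(s$partner_b[[1]]$sequence, toy$sequence_b)
  # a chain absent from the file is a fatal error naming the chain
  path <- write_toy_complex(toy)
  expect_error(load_complex(path, list("A", "C"), quiet = TRUE), "C")
  # partner groups must be disjoint
  expect_error(load_complex(path, list("A", "A"), quiet = TRUE), "disjoint")
})

test_that("selenomethionine maps to M; unknown residues are skipped", {
  toy <- make_toy_complex(5, 4, seed = 2)
  lines <- toy$pdb_text
  # rewrite the residue name of chain A position 2 to MSE, position 3 to XYZ
  lines <- vapply(lines, function(l) {
    if (startsWith(l, "ATOM") && substr(l, 22, 22) == "A") {
      resno <- as.integer(substr(l, 23, 26))
      if (resno == 2L) substr(l, 18, 20) <- "MSE"
      if (resno == 3L) substr(l, 18, 20) <- "XYZ"
    }
    l
  }, "", USE.NAMES = FALSE)
  path <- tempfile(fileext = ".pdb")
  writeLines(lines, path)
  s <- load_complex(path, toy$partner_spec, quiet = TRUE)
  expect_equal(nchar(s$partner_a[[1]]$sequence), 4L)  # XYZ residue dropped
  expect_equal(substr(s$partner_a[[1]]$sequence, 2, 2), "M")
})

test_that("apply_mutation substitutes exactly one residue and inverts", {
  ch <- chain_sequence("A", "ACDEF", 10:14)
  mut <- apply_mutation(ch, mutation_spec("A", "11", "C", "W"))
  expect_equal(mut$sequence, "AWDEF")
  expect_equal(mut$numbering, ch$numbering)
  # WT mismatch and absent position are errors
  expect_error(apply_mutation(ch, mutation_spec("A", "11", "D", "W")),
               "WT mismatch")
  expect_error(apply_mutation(ch, mutation_spec("A", "99", "C", "W")),
               "99")
  expect_error(apply_mutation(ch, mutation_spec("B", "11", "C", "W")),
               "chain")
  # involution: applying the reverse restores the original
  back <- apply_mutation(mut, mutation_spec("A", "11", "W", "C"))
  expect_identical(back, ch)
})

test_that("interface detection respects the inclusive cutoff boundary", {
  # hand-built complex: single-residue chains at controlled CA distances
  make_pair <- function(dist) {
    lines <- c(
      sprintf("ATOM  %5d  CA  ALA A   1    %8.3f%8.3f%8.3f  1.00  0.00           C",
              1L, 0, 0, 0),
      sprintf("ATOM  %5d  CA  GLY B   1    %8.3f%8.3f%8.3f  1.00  0.00           C",
              2L, dist, 0, 0),
      "END")
    path <- tempfile(fileext = ".pdb")
    writeLines(lines, path)
    load_complex(path, list("A", "B"), quiet = TRUE)
  }
  expect_equal(nrow(interface_positions(make_pair(3.9), 4.0)), 2L)
  expect_equal(nrow(interface_positions(make_pair(4.0), 4.0)), 2L)  # inclusive
  expect_equal(nrow(interface_positions(make_pair(4.1), 4.0)), 0L)
})

test_that("interface set is symmetric, empty at cutoff 0, monotone in cutoff", {
  s <- small_structure()
  ip <- interface_positions(s, 4.0)
  expect_gt(nrow(ip), 0L)
  swapped <- s
  swapped$partner_a <- s$partner_b
  swapped$partner_b <- s$partner_a
  ip_sw <- interface_positions(swapped, 4.0)
  key <- function(df) sort(paste(df$chain_id, df$position))
  expect_equal(key(ip), key(ip_sw))
  expect_equal(nrow(interface_positions(s, 0)), 0L)
  sizes <- vapply(c(0, 2, 4, 6, 10, 50), function(cut)
    nrow(interface_positions(s, cut)), 0L)
  expect_true(all(diff(sizes) >= 0))
})
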