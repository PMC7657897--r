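test_that("reference positions map through gaps correctly", {
  msa <- seq_records(c("REF", "q"), c("AC-GT", "ACCGT"), "protein")
  got <- map_ref_positions(msa, 3L, ref_id = "REF")
  expect_equal(got$column, 4L) # gap-skipping definition
  # gapless reference: identity
  msa2 <- seq_records(c("REF", "q"), c("ACDEF", "ACDEF"), "protein")
  expect_equal(map_ref_positions(msa2, 1:5, ref_id = "REF")$column, 1:5)
  # errors
  expect_error(map_ref_positions(msa, 1L, ref_id = "nope"), "not found")
  expect_error(map_ref_positions(msa, 5L, ref_id = "REF"), "beyond")
})

test_that("position mapping agrees with a cursor-walk oracle on random gapped rows", {
  withr::local_seed(5)
  aa <- c("A", "C", "D", "E", "F", "G")
  for (i in 1:30) {
    width <- sample(20:60, 1)
    chars <- sample(c(aa, "-"), width, replace = TRUE,
                    prob = c(rep(0.13, 6), 0.22))
    if (all(chars == "-")) chars[1] <- "A"
    row <- paste(chars, collapse = "")
    msa <- seq_records(c("REF", "other"),
                       c(row, paste(sample(aa, width, TRUE), collapse = "")),
                       "protein")
    ungapped <- sum(chars != "-")
    pos <- sort(sample.int(ungapped, min(5L, ungapped)))
    got <- map_ref_positions(msa, pos, ref_id = "REF")
    expect_equal(got$column, vapply(pos, oracle_ref_column, integer(1),
                                    ref_row = row))
  }
})

test_that("diagnostic states read match/divergent/gap with X flagged", {
  ref <- random_protein_ref()
  spec <- toy_spec()
  chars <- strsplit(ref$residues, "")[[1]]
  chars[spec$positions$pos] <- spec$positions$expected
  good <- paste(chars, collapse = "")
  gapped <- chars; gapped[55] <- "-"
  amb <- chars; amb[10] <- "X"
  msa <- seq_records(c("REF", "intact", "gapped", "ambiguous"),
                     c(good, good, paste(gapped, collapse = ""),
                       paste(amb, collapse = "")), "protein")
  st <- extract_states(msa, spec)
  expect_true(all(dplyr::filter(st, seq_id == "intact")$state == "match"))
  g <- dplyr::filter(st, seq_id == "gapped", name == "Gln1")
  expect_equal(g$state, "gap")
  x <- dplyr::filter(st, seq_id == "ambiguous", name == "Cys")
  expect_equal(x$state, "divergent")
  expect_equal(x$flag, "ambiguous residue")
})

test_that("the decision table is total and deterministic over all 243 state combinations", {
  states <- c("match", "divergent", "gap")
  grid <- expand.grid(t1 = states, t2 = states, t3 = states,
                      g1 = states, g2 = states,
                      stringsAsFactors = FALSE)
  expect_equal(nrow(grid), 243L)
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    call <- classify_cps(states_from_labels(
      c(g$t1, g$t2, g$t3), c(g$g1, g$g2)
    ))
    # independent restatement of the rule
    expected <- if (any(g == "gap")) {
      "INDETERMINATE"
    } else if (!any(c(g$t1, g$t2, g$t3) == "divergent")) {
      ngl <- sum(c(g$g1, g$g2) == "divergent")
      c("GLN_UTILIZING", "INTERMEDIATE_AMMONIA_PREFERRING",
        "AMMONIA_OBLIGATE")[ngl + 1L]
    } else {
      "AMMONIA_OBLIGATE"
    }
    expect_equal(call$functional_class, expected,
                 info = paste(unlist(g), collapse = ","))
  }
})

test_that("canonical CPS configurations classify as expected", {
  m <- "match"; d <- "divergent"
  # teleost CPS III: triad + both gln residues intact -> glutamine user
  expect_equal(classify_cps(states_from_labels(c(m, m, m), c(m, m))
               )$functional_class, "GLN_UTILIZING")
  # Alcolapia / tree frog: triad intact, one gln residue lost
  expect_equal(classify_cps(states_from_labels(c(m, m, m), c(m, d))
               )$functional_class, "INTERMEDIATE_AMMONIA_PREFERRING")
  # bullfrog CPS I: triad intact, both gln residues lost
  expect_equal(classify_cps(states_from_labels(c(m, m, m), c(d, d))
               )$functional_class, "AMMONIA_OBLIGATE")
  # terrestrial CPS I: catalytic Cys lost
  expect_equal(classify_cps(states_from_labels(c(d, m, m), c(m, m))
               )$functional_class, "AMMONIA_OBLIGATE")
  # gap in the triad: no call
  expect_equal(classify_cps(states_from_labels(c("gap", m, m), c(m, m))
               )$functional_class, "INDETERMINATE")
})

test_that("calls carry tidy states, glance counts and a state heat map", {
  ref <- random_protein_ref()
  spec <- toy_spec()
  sim <- sim_protein_family(ref, spec, n_seqs = 4,
                            classes = c("GLN_UTILIZING", "AMMONIA_OBLIGATE"),
                            sub_prob = 0, seed = 2)
  calls <- classify_alignment(sim$msa, spec)
  expect_equal(nrow(tidy(calls)), 5L * nrow(sim$msa))
  gl <- glance(calls)
  expect_equal(gl$n_sequences, nrow(sim$msa))
  expect_equal(gl$gln_utilizing + gl$intermediate_ammonia_preferring +
                 gl$ammonia_obligate + gl$indeterminate, nrow(sim$msa))
  expect_s3_class(ggplot2::autoplot(calls), "ggplot")
})

test_that("column conservation excludes gaps and flags undefined columns", {
  msa <- seq_records(paste0("s", 1:10),
                     c(rep("CA-", 5), rep("CS-", 5)), "protein")
  cons <- column_conservation(msa, threshold = 0.9)
  expect_equal(cons$fraction[1], 1.0) # all C
  expect_equal(cons$fraction[2], 0.5) # 5 A, 5 S
  expect_true(is.na(cons$fraction[3])) # all gaps
  expect_true(cons$conserved[1])
  expect_false(cons$conserved[2])
  expect_error(column_conservation(msa[1, ]), "at least 2 rows")
})

test_that("diagnostic specs round-trip through YAML and validate", {
  spec <- toy_spec()
  f <- withr::local_tempfile(fileext = ".yaml")
  write_diagnostic_spec(spec, f)
  back <- read_diagnostic_spec(f)
  expect_equal(back$positions, spec$positions)
  expect_equal(back$ref_id, spec$ref_id)
  expect_error(diagnostic_spec("r", c(Cys = 1, His = 2, Glu = 1),
                               c(3, 4)), "distinct")
  expect_error(diagnostic_spec("r", c(A = 1, B = 2, C = 3), c(4, 5)),
               "Cys, His, Glu")
  # shipped template parses
  tmpl <- read_diagnostic_spec(
    system.file("extdata", "diagnostic_spec_template.yaml",
                package = "cpscan")
  )
  expect_s3_class(tmpl, "diagnostic_spec")
  expect_equal(tmpl$window, c(278L, 397L))
})
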