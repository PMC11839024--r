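test_that("structure files round-trip through PDB exactly", {
  m <- gen_structure(c(12, 8), plddt = list(rep(85, 12), rep(65, 8)), seed = 2)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(m, f)
  back <- load_structure(f, m$chain_map, source = "pairwise-prediction",
                         model_id = m$model_id)
  expect_equal(back$atoms[c("chain", "resno", "x", "y", "z", "plddt")],
               m$atoms[c("chain", "resno", "x", "y", "z", "plddt")])
})

test_that("chain-map offsets reconcile structure and full-length numbering", {
  m <- gen_structure(10, offsets = 10L, accessions = "P1", seed = 1)
  res <- model_positions(m)
  expect_equal(res$position[res$resno == 1], 11)

  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(m, f)
  expect_error(
    load_structure(f, data.frame(chain = c("A", "B"), accession = c("P1", "P2"),
                                 offset = 0L)),
    "B")
})

test_that("Calpha distances equal the longhand formula", {
  atoms <- data.frame(chain = "A", resno = 1:2,
                      x = c(0, 3), y = c(0, 4), z = c(0, 0), plddt = 90)
  m <- structure_model(atoms, data.frame(chain = "A", accession = "P1",
                                         offset = 0L))
  expect_equal(ca_distance(m, "P1", 1, "P1", 2), 5.0)
  expect_equal(ca_distance(m, "P1", 1, "P1", 1), 0.0)

  rw <- gen_structure(c(30, 30), fold = "random-walk", seed = 4)
  res <- model_positions(rw)
  set.seed(1)
  for (k in 1:20) {
    i <- sample(nrow(res), 2)
    d_pkg <- ca_distance(rw, res$accession[i[1]], res$position[i[1]],
                         res$accession[i[2]], res$position[i[2]])
    d_hand <- longhand_distance(res, res$accession[i[1]], res$position[i[1]],
                                res$accession[i[2]], res$position[i[2]])
    expect_equal(d_pkg, d_hand, tolerance = 1e-9)
  }
})

test_that("distance evaluation statuses partition every link", {
  atoms <- data.frame(
    chain = rep(c("A", "B"), each = 3), resno = rep(1:3, 2),
    x = c(0, 3.8, 7.6, 0, 3.8, 7.6),
    y = c(0, 0, 0, 34, 36, 20),
    z = 0,
    plddt = c(90, 90, 65, 90, 90, 70))
  cm <- data.frame(chain = c("A", "B"), accession = c("P1", "P2"),
                   offset = c(0L, 0L))
  m <- structure_model(atoms, cm)
  links <- data.frame(
    accession_a = "P1", pos_a = c(1, 2, 3, 1, 1),
    accession_b = "P2", pos_b = c(1, 2, 2, 3, 9))
  ev <- evaluate_crosslinks(m, links, threshold = 35, plddt_min = 70)
  # d(A1,B1)=34 within; d(A2,B2)=36 exceeded; A3 pLDDT 65 -> unstructured;
  # B3 pLDDT exactly 70 -> unstructured (strict >70); P2 pos 9 unmapped
  expect_equal(ev$status,
               c("within", "exceeded", "unstructured", "unstructured", "unmapped"))
  expect_true(all(table(ev$status)[c("within", "exceeded")] == 1))
  g <- glance(ev)
  expect_equal(g$frac_within, 0.5)
  expect_equal(g$n_unstructured, 2)
  expect_equal(g$n_unmapped, 1)

  # the gate can be disabled (experimental structures have no pLDDT)
  no_gate <- evaluate_crosslinks(m, links, threshold = 35, gate_plddt = FALSE)
  expect_false("unstructured" %in% no_gate$status)

  # boundary: a link at exactly the threshold counts as within
  at <- data.frame(accession_a = "P1", pos_a = 1, accession_b = "P2", pos_b = 1)
  expect_equal(evaluate_crosslinks(m, at, threshold = 34)$status, "within")
})

test_that("fraction within range is monotone in the threshold", {
  m <- gen_structure(c(40, 40), chain_spacing = 12, seed = 6)
  links <- gen_crosslinks(m, 20, 20, seed = 7)
  fracs <- vapply(c(10, 20, 30, 35, 50, 100), function(t) {
    glance(evaluate_crosslinks(m, links, threshold = t))$frac_within
  }, numeric(1))
  expect_true(all(diff(fracs) >= 0))
})

test_that("prediction triage follows score then distance-agreement rules", {
  mk_ev <- function(statuses, intra = FALSE) {
    tibble::tibble(status = statuses, is_intra = intra)
  }
  expect_equal(classify_prediction(mk_ev(c("within", "within")), spoc = 0.8),
               "supported")
  expect_equal(classify_prediction(mk_ev(c("unstructured", "unmapped")),
                                   spoc = 0.8),
               "unstructured-only")
  expect_equal(classify_prediction(mk_ev("within"), spoc = 0.2),
               "low-confidence")
  # SPOC exactly at the floor is not enough (strict > 0.33)
  expect_equal(classify_prediction(mk_ev("within"), spoc = 0.33),
               "low-confidence")
  # exactly half within is not a majority
  expect_equal(classify_prediction(mk_ev(c("within", "exceeded")), spoc = 0.8),
               "violated")
  expect_equal(classify_prediction(mk_ev(c("within", "within", "exceeded")),
                                   spoc = 0.8),
               "supported")
  # order invariance
  ev <- mk_ev(c("exceeded", "within", "unstructured", "within"))
  expect_equal(classify_prediction(ev, spoc = 0.9),
               classify_prediction(ev[c(3, 1, 4, 2), ], spoc = 0.9))
  # missing SPOC without an ipTM floor is unscored
  expect_equal(classify_prediction(mk_ev("within"), spoc = NA), "unscored")
  expect_equal(classify_prediction(mk_ev("within"), spoc = NA, iptm = 0.9,
                                   iptm_min = 0.5), "supported")
  expect_warning(
    out <- classify_prediction(mk_ev("within", intra = TRUE), spoc = 0.9),
    "no interprotein")
  expect_true(is.na(out))
})

test_that("trimer acceptance needs two interfaces strictly above 0.5", {
  expect_true(trimer_quality(c(0.9, 0.6, 0.1)))
  expect_false(trimer_quality(c(0.9, 0.5, 0.5)))  # strict >
  expect_true(trimer_quality(c(0.51, 0.51, 0.51)))
  expect_false(trimer_quality(c(0.9, NA)))        # missing interfaces are 0
  expect_true(trimer_quality(c(0.6, 0.6)))
})

test_that("contact residues come from a direct distance scan", {
  m <- gen_structure(c(20, 20), chain_spacing = 6, seed = 3)
  res <- model_positions(m)
  got <- contact_residues(m, "A", "B", cutoff = 8)
  a <- res[res$chain == "A", ]; b <- res[res$chain == "B", ]
  for (ch in c("A", "B")) {
    this <- if (ch == "A") a else b
    other <- if (ch == "A") b else a
    oracle <- this$position[vapply(seq_len(nrow(this)), function(i) {
      any(sqrt((this$x[i] - other$x)^2 + (this$y[i] - other$y)^2 +
                 (this$z[i] - other$z)^2) <= 8)
    }, logical(1))]
    expect_setequal(got$position[got$chain == ch], oracle)
  }

  far <- gen_structure(c(10, 10), chain_spacing = 50, seed = 3)
  expect_equal(nrow(contact_residues(far, "A", "B", cutoff = 8)), 0)

  c8 <- contact_residues(m, "A", "B", cutoff = 8)
  c10 <- contact_residues(m, "A", "B", cutoff = 10)
  expect_true(all(paste(c8$chain, c8$position) %in% paste(c10$chain, c10$position)))
})

test_that("variant scan uses sequence distance with an inclusive window", {
  contacts <- data.frame(accession = "P1", position = 78L)
  v <- data.frame(accession = "P1", position = c(78L, 80L, 81L),
                  ref = "R", alt = "L")
  out <- variant_interface_scan(v, contacts, window = 2)
  expect_equal(out$near_interface, c(TRUE, TRUE, FALSE))
  expect_equal(out$gap, c(0, 2, 3))
  expect_equal(out$nearest_contact, rep(78, 3))

  expect_warning(
    flagged <- variant_interface_scan(v, contacts, window = 2,
                                      sequence_lengths = c(P1 = 79)),
    "beyond sequence")
  expect_equal(flagged$out_of_range, c(FALSE, TRUE, TRUE))

  none <- variant_interface_scan(v[0, ], contacts)
  expect_equal(nrow(none), 0)
})

test_that("pseudobond export is deterministic and round-trips link counts", {
  m <- gen_structure(c(30, 30), chain_spacing = 8, seed = 5)
  links <- gen_crosslinks(m, 10, 5, seed = 6)
  ev <- evaluate_crosslinks(m, links, threshold = 35)
  f <- withr::local_tempfile(fileext = ".pb")
  export_pseudobonds(ev, f)
  lines <- readLines(f)
  expect_match(lines[1], "^;")
  body <- lines[-1]
  expect_equal(length(body), sum(ev$status != "unmapped"))
  expect_true(all(grepl("^/[A-Z]:\\d+@CA /[A-Z]:\\d+@CA #", body)))

  one <- evaluate_crosslinks(m, links[1, ], threshold = 35)
  f2 <- withr::local_tempfile(fileext = ".pb")
  export_pseudobonds(one, f2)
  expect_equal(length(readLines(f2)), 2)

  f3 <- withr::local_tempfile(fileext = ".pb")
  export_pseudobonds(ev[0, ], f3)
  expect_equal(length(readLines(f3)), 1)  # header only
})
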