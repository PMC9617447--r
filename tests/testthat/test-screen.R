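make_labels <- function(n_ag, n_anti, n_inact = 0) {
  data.frame(
    molecule_id = c(sprintf("AG%02d", seq_len(n_ag)),
                    sprintf("AN%02d", seq_len(n_anti)),
                    if (n_inact) sprintf("IN%02d", seq_len(n_inact))),
    class = c(rep("agonist", n_ag), rep("antagonist", n_anti),
              rep("inactive", n_inact)),
    stringsAsFactors = FALSE
  )
}

decide <- function(labels, selected) {
  data.frame(molecule_id = labels$molecule_id,
             decision = ifelse(labels$molecule_id %in% selected,
                               "agonist", "non_agonist"),
             stringsAsFactors = FALSE)
}

test_that("molecule classification follows the any-inlier union rule", {
  expect_equal(classify_molecule(c(-1.2, -0.2, 0.3)), "agonist")
  expect_equal(classify_molecule(c(-1, -2, -0.1)), "non_agonist")
  expect_warning(d <- classify_molecule(numeric(0)), "zero poses")
  expect_equal(d, "non_agonist")

  # agonist under structure A only, pooled over {A, B} -> agonist
  poses <- data.frame(molecule_id = c("m1", "m1", "m2"),
                      receptor = c("A", "B", "A"),
                      score = c(0.2, -3, -1))
  dec <- classify_molecules(poses)
  expect_equal(dec$decision[dec$molecule_id == "m1"], "agonist")
  expect_equal(dec$decision[dec$molecule_id == "m2"], "non_agonist")
})

test_that("evaluate_screen reproduces the printed worked examples", {
  # 19 agonists + 17 antagonists, 16 selected of which 15 agonists
  lab <- make_labels(19, 17)
  dec <- decide(lab, c(sprintf("AG%02d", 1:15), "AN01"))
  met <- evaluate_screen(dec, lab)
  expect_equal(met$counts[["TP"]], 15)
  expect_equal(round(met$precision, 2), 0.94)
  expect_equal(round(met$recall, 2), 0.79)
  expect_equal(met$n_selected, 16)
  expect_equal(met$n_total, 36)

  # everything selected: recall 1.00, precision 19/36
  met_all <- evaluate_screen(decide(lab, lab$molecule_id), lab)
  expect_equal(met_all$recall, 1)
  expect_equal(round(met_all$precision, 2), 0.53)

  # nothing selected: all-zero conventions
  met_none <- evaluate_screen(decide(lab, character(0)), lab)
  expect_equal(c(met_none$precision, met_none$recall, met_none$f1),
               c(0, 0, 0))

  # confusion-count invariants
  expect_equal(met$counts[["TP"]] + met$counts[["FN"]], 19)
  expect_equal(met$counts[["FP"]] + met$counts[["TN"]], 17)

  ghost <- data.frame(molecule_id = "GHOST", decision = "agonist")
  expect_error(evaluate_screen(ghost, lab), "unlabeled")
})

test_that("evaluation is permutation invariant and F1 consistent", {
  set.seed(12)
  lab <- make_labels(10, 8, 5)
  sel <- sample(lab$molecule_id, 9)
  met <- evaluate_screen(decide(lab, sel), lab)
  perm <- sample(nrow(lab))
  met_p <- evaluate_screen(decide(lab, sel)[perm, ], lab)
  expect_equal(met_p$counts, met$counts)
  if (met$precision + met$recall > 0) {
    expect_equal(met$f1, 2 * met$precision * met$recall /
                   (met$precision + met$recall))
  }
})

test_that("ensemble recall is at least any single-structure recall", {
  set.seed(66)
  lab <- make_labels(12, 10)
  for (r in 1:20) {
    scoresA <- stats::setNames(stats::rnorm(22), lab$molecule_id)
    scoresB <- stats::setNames(stats::rnorm(22), lab$molecule_id)
    decA <- decide(lab, names(scoresA)[scoresA >= 0])
    decB <- decide(lab, names(scoresB)[scoresB >= 0])
    decU <- decide(lab, union(names(scoresA)[scoresA >= 0],
                              names(scoresB)[scoresB >= 0]))
    rA <- evaluate_screen(decA, lab)$recall
    rB <- evaluate_screen(decB, lab)$recall
    rU <- evaluate_screen(decU, lab)$recall
    expect_gte(rU, max(rA, rB))
  }
})

test_that("binary IFPs, averaging mask and Tanimoto behave per definition", {
  uni <- c("SER.207", "ASP.113", "ASN.312")
  tr <- triplet1("HBA", c(0, 0, 0), c(3, 0, 0), "SER", 207L)
  ifp <- compute_ifp(tr, uni)
  expect_equal(sum(ifp), 1)
  expect_equal(unname(ifp["SER.207|HBA"]), 1L)
  expect_error(compute_ifp(triplet1("HBA", c(0, 0, 0), c(3, 0, 0),
                                    "TRP", 99L), uni), "outside")

  # 100 frames: present in 9 -> masked, in 10 -> shown, crystal overrides
  empty <- compute_ifp(tr[integer(0), , drop = FALSE], uni)
  mk_list <- function(n_on) c(replicate(n_on, ifp, simplify = FALSE),
                              replicate(100 - n_on, empty, simplify = FALSE))
  avg9 <- average_ifp(mk_list(9))
  avg10 <- average_ifp(mk_list(10))
  expect_false(avg9$shown[avg9$bit == "SER.207|HBA"])
  expect_true(avg10$shown[avg10$bit == "SER.207|HBA"])
  crystal <- compute_ifp(tr, uni)
  avg0 <- average_ifp(mk_list(0), crystal = crystal)
  expect_true(avg0$shown[avg0$bit == "SER.207|HBA"])

  a <- empty; a[c(1, 2, 3)] <- 1L
  b <- empty; b[c(2, 3, 4)] <- 1L
  expect_equal(ifp_tanimoto(a, b), 0.5)  # 2 shared of 4 in the union
  expect_equal(ifp_tanimoto(a, a), 1)
  d <- empty; d[5] <- 1L
  expect_equal(ifp_tanimoto(a, d), 0)
  expect_warning(z <- ifp_tanimoto(empty, empty), "empty")
  expect_equal(z, 0)
  expect_error(ifp_tanimoto(a, a[1:5]), "mismatch")
})

test_that("optimal_threshold maximises F1 with lowest-threshold ties", {
  lab <- make_labels(3, 3)
  # perfectly separated: F1 = 1, lowest candidate in the gap returned
  sc <- stats::setNames(c(5, 6, 7, 1, 2, 3), lab$molecule_id)
  res <- optimal_threshold(sc, lab)
  expect_equal(res$metrics$f1, 1)
  expect_equal(res$threshold, 4)

  # inverted scores: best F1 equals the all-selected baseline
  sc_inv <- stats::setNames(c(1, 2, 3, 5, 6, 7), lab$molecule_id)
  res_inv <- optimal_threshold(sc_inv, lab)
  all_sel <- evaluate_screen(decide(lab, lab$molecule_id), lab)
  expect_equal(res_inv$metrics$f1, all_sel$f1)
  expect_equal(res_inv$threshold, 1)

  # noisy planted gap recovered
  set.seed(100)
  lab2 <- make_labels(15, 15)
  sc2 <- stats::setNames(c(stats::rnorm(15, 3, 0.4),
                           stats::rnorm(15, 0, 0.4)), lab2$molecule_id)
  res2 <- optimal_threshold(sc2, lab2)
  expect_gt(res2$threshold, 0.5)
  expect_lt(res2$threshold, 2.8)
  expect_gt(res2$metrics$f1, 0.9)

  expect_warning(dg <- optimal_threshold(
    stats::setNames(rep(2, 6), lab$molecule_id), lab), "identical")
  expect_equal(dg$threshold, 2)
})
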