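test_that("the importance schedule is geometric, decreasing and sums below 1", {
  for (L in 1:5) {
    ic <- ic_schedule(L)
    expect_equal(ic, 2^(-(1:L)))
    expect_true(all(diff(ic) < 0) || L == 1)
    expect_equal(sum(ic), 1 - 2^(-L), tolerance = 1e-15)
  }
})

test_that("per-layer scores sum normalized weights of neighbours carrying each term", {
  fx <- fig5_fixture()
  # single shared-complex neighbour with normalized weight 1
  scl <- layer_score(fx$tensor, "SCL", "A", fx$ann)
  expect_equal(scl[["f3"]], 1)
  expect_equal(scl[["f4"]], 1)
  # two equally weighted physical neighbours each contribute 0.5
  pil <- layer_score(fx$tensor, "PIL", "A", fx$ann)
  expect_equal(sort(names(pil)), paste0("f", 1:5))
  expect_equal(unname(pil[paste0("f", 1:5)]), rep(0.5, 5))
  # a protein isolated on a layer yields the empty map
  expect_length(layer_score(fx$tensor, "SCL", "C", fx$ann), 0L)
  expect_error(layer_score(fx$tensor, "SCL", "ZZ", fx$ann), "unknown query")
})

test_that("two equal-weight neighbours sharing a term give it the full row mass", {
  universe <- c("Q", "X", "Y")
  layer <- build_scl(read_complexes(write_lines_tmp(c("Q\tX", "Q\tY")), universe))
  net <- assemble(list(layer), order = "SCL")
  tensor <- normalize_tensor(net)
  ann <- annotation_map(data.frame(protein = c("X", "Y"), term = "f"), "BP", universe)
  s <- layer_score(tensor, "SCL", "Q", ann)
  expect_equal(s[["f"]], 1, tolerance = 1e-12)
})

test_that("composite scores accumulate layer scores under the geometric schedule", {
  comp <- composite_score(list(c(f = 1), c(f = 0.72), c(f = 0.5)))
  expect_equal(comp[["f"]], 0.7425, tolerance = 1e-12)
  expect_equal(composite_score(list(numeric(0), numeric(0), c(f = 0.5)))[["f"]],
               0.0625, tolerance = 1e-12)
  expect_equal(composite_score(list(numeric(0), c(f = 0.28), c(f = 0.5)))[["f"]],
               0.1325, tolerance = 1e-12)
})

test_that("the anchor neighbour is the highest-raw-weight annotated neighbour", {
  fx <- fig5_fixture()
  sel <- select_n(fx$net, "A", fx$ann)
  expect_equal(sel$anchor, "B")   # raw SCL weight 1 beats 0.72, 0.5
  expect_equal(sel$n_limit, 2L)   # B carries f3, f4

  # tie on raw weight resolved toward the lexicographically smaller protein
  universe <- c("Q", "X", "Y")
  layer <- build_scl(read_complexes(write_lines_tmp(c("Q\tX", "Q\tY")), universe))
  net1 <- assemble(list(layer), order = "SCL")
  ann <- annotation_map(data.frame(protein = c("X", "Y", "Y"),
                                   term = c("fa", "fb", "fc")), "BP", universe)
  sel_tie <- select_n(net1, "Q", ann)
  expect_equal(sel_tie$anchor, "X")
  expect_equal(sel_tie$n_limit, 1L)

  # no annotated neighbour anywhere: empty prediction
  ann_none <- annotation_map(data.frame(protein = "Q", term = "fz"), "BP", universe)
  sel_none <- select_n(net1, "X", ann_none)  # X's only neighbour is unannotated Q? Q is annotated
  expect_equal(sel_none$anchor, "Q")
  ann_empty <- annotation_map(data.frame(protein = character(), term = character()),
                              "BP", universe)
  sel0 <- select_n(net1, "Q", ann_empty)
  expect_equal(sel0$n_limit, 0L)
  expect_true(is.na(sel0$anchor))
})

test_that("the worked example ranks f3 and f4 first at 0.7425 and selects exactly them", {
  fx <- fig5_fixture()
  pred <- predict_functions(fx$net, fx$query, fx$ann, tensor = fx$tensor)
  expect_equal(pred$term[1:2], c("f3", "f4"))  # tie broken by term id
  expect_equal(pred$score[1:2], c(0.7425, 0.7425), tolerance = 1e-12)
  expect_equal(pred$score[pred$term == "f1"], 0.1325, tolerance = 1e-12)
  expect_equal(pred$score[pred$term == "f2"], 0.1325, tolerance = 1e-12)
  expect_equal(pred$score[pred$term == "f5"], 0.0625, tolerance = 1e-12)
  expect_equal(selected_terms(pred), c("f3", "f4"))
  expect_equal(attr(pred, "anchor"), "B")

  pl <- per_layer_scores(pred)
  expect_equal(pl$s[pl$layer == "SDL" & pl$term == "f3"], 0.72, tolerance = 1e-12)
  expect_equal(pl$s[pl$layer == "SDL" & pl$term == "f1"], 0.28, tolerance = 1e-12)
})

test_that("a single-layer schedule is a monotone transform of the raw layer score", {
  universe <- c("Q", "X", "Y")
  layer <- build_scl(read_complexes(write_lines_tmp(c("Q\tX\tY", "Q\tX")), universe))
  net <- assemble(list(layer), order = "SCL")
  ann <- annotation_map(data.frame(protein = c("X", "X", "Y"),
                                   term = c("fa", "fb", "fb")), "BP", universe)
  pred <- predict_functions(net, "Q", ann)
  s <- layer_score(normalize_tensor(net), "SCL", "Q", ann)
  expect_equal(setNames(pred$score, pred$term)[names(s)], s / 2, tolerance = 1e-12)
})

test_that("composite scores match the brute-force tensor oracle on random networks", {
  for (seed in 1:10) {
    synth <- small_synth(seed)
    net <- synthetic_network(synth)
    tensor <- normalize_tensor(net)
    sets <- annotation_sets(synth$ann)
    queries <- with_seed_sample(seed, synth$universe, 4)
    for (q in queries) {
      masked <- sets[setdiff(names(sets), q)]
      ann_masked <- annotation_map(
        data.frame(protein = rep(names(masked), lengths(masked)),
                   term = unlist(masked, use.names = FALSE)),
        "BP", synth$universe)
      pred <- predict_functions(net, q, ann_masked, tensor = tensor)
      expected <- oracle_composite(net, q, masked)
      got <- setNames(pred$score, pred$term)
      expect_equal(sort(names(got)), sort(names(expected)))
      if (length(expected)) {
        expect_equal(got[names(expected)], expected[names(expected)], tolerance = 1e-12)
      }
    }
  }
})

test_that("composite scores are bounded in [0, 1) and grow with supporting layers", {
  synth <- small_synth(seed = 17)
  net3 <- synthetic_network(synth)
  sets <- annotation_sets(synth$ann)
  # two-layer subnetwork: dropping a layer never increases a term's score
  net2 <- assemble(list(net3$layers[["SCL"]], net3$layers[["SDL"]]),
                   order = c("SCL", "SDL"))
  for (q in synth$universe[1:10]) {
    p3 <- predict_functions(net3, q, synth$ann)
    expect_true(all(p3$score >= 0 & p3$score < 1))
    p2 <- predict_functions(net2, q, synth$ann)
    s3 <- setNames(p3$score, p3$term)
    s2 <- setNames(p2$score, p2$term)
    common <- intersect(names(s2), names(s3))
    expect_true(all(s3[common] >= s2[common] - 1e-12))
  }
})

test_that("permuting the access order re-indexes the importance coefficients exactly", {
  synth <- small_synth(seed = 23)
  net <- synthetic_network(synth, order = c("SCL", "SDL", "PIL"))
  net_perm <- synthetic_network(synth, order = c("PIL", "SCL", "SDL"))
  sets <- annotation_sets(synth$ann)
  for (q in synth$universe[1:6]) {
    pred <- predict_functions(net_perm, q, synth$ann)
    pl <- per_layer_scores(predict_functions(net, q, synth$ann))
    # recompute by hand with IC indexed by the permuted positions
    ic <- c(PIL = 1 / 2, SCL = 1 / 4, SDL = 1 / 8)
    expected <- tapply(pl$s * ic[pl$layer], pl$term, sum)
    got <- setNames(pred$score, pred$term)
    if (length(expected)) {
      expect_equal(got[names(expected)], setNames(as.numeric(expected), names(expected)),
                   tolerance = 1e-12)
    }
  }
})

test_that("held-out annotations cannot leak into the candidate set", {
  # the query carries a unique term nobody else has; after masking, that term
  # must be absent from its candidates
  universe <- c("Q", "X", "Y")
  layer <- build_scl(read_complexes(write_lines_tmp(c("Q\tX\tY")), universe))
  net <- assemble(list(layer), order = "SCL")
  ann <- annotation_map(data.frame(protein = c("Q", "X", "Y"),
                                   term = c("secret", "fa", "fa")), "BP", universe)
  masked <- annotation_map(ann[ann$protein != "Q", ], "BP", universe)
  pred <- predict_functions(net, "Q", masked)
  expect_false("secret" %in% pred$term)
  expect_true("fa" %in% pred$term)
})

test_that("neighbour counting ranks by frequency with term-id ties and anchor-bounded selection", {
  universe <- c("Q", "N1", "N2", "N3")
  layer <- build_scl(read_complexes(
    write_lines_tmp(c("Q\tN1", "Q\tN2", "Q\tN3")), universe))
  ann <- annotation_map(data.frame(protein = c("N1", "N2", "N3", "Q"),
                                   term = c("f1", "f1", "f2", "f1")), "BP", universe)
  preds <- nc_layer_baseline(layer, ann)
  q_rows <- preds[preds$protein == "Q", ]
  expect_equal(q_rows$term, c("f1", "f2"))
  expect_equal(q_rows$freq, c(2L, 1L))

  # frequency tie resolved by term id
  ann_tie <- annotation_map(data.frame(protein = c("N1", "N2", "Q"),
                                       term = c("f2", "f1", "f1")), "BP", universe)
  tie_rows <- nc_layer_baseline(layer, ann_tie)
  tie_rows <- tie_rows[tie_rows$protein == "Q", ]
  expect_equal(tie_rows$term, c("f1", "f2"))

  # all neighbours unannotated: no prediction rows for that protein
  ann_none <- annotation_map(data.frame(protein = "Q", term = "f1"), "BP", universe)
  expect_equal(nrow(nc_layer_baseline(layer, ann_none)), 0L)
})

test_that("layer ordering puts the function-sharing layer first and useless layers last", {
  # layer GOOD: every neighbour shares the holdout's function
  # layer BAD: neighbours never share it
  universe <- c(paste0("G", 1:6), paste0("H", 1:6))
  good_members <- paste(c(paste0("G", 1:3)), collapse = "\t")
  good_members2 <- paste(c(paste0("G", 4:6)), collapse = "\t")
  bad_pairs <- c("G1\tH1", "G2\tH2", "G3\tH3")
  good <- build_scl(read_complexes(write_lines_tmp(c(good_members, good_members2)), universe))
  bad_layer <- build_sdl(read_domains(write_lines_tmp(
    c("G1\tdx", "H1\tdx", "G2\tdy", "H2\tdy", "G3\tdz", "H3\tdz")), universe))
  ann <- annotation_map(data.frame(
    protein = c(paste0("G", 1:3), paste0("G", 4:6), paste0("H", 1:3)),
    term = c(rep("fA", 3), rep("fB", 3), rep("fC", 3))), "BP", universe)
  net <- assemble(list(good, bad_layer), order = c("SDL", "SCL"))
  stats <- determine_layer_order(net, ann)
  expect_equal(attr(stats, "order"), c("SCL", "SDL"))
  expect_gt(stats$f_measure[stats$layer == "SCL"], stats$f_measure[stats$layer == "SDL"])
  expect_equal(stats$f_measure[stats$layer == "SCL"], 1)

  # single layer: trivially that layer
  net1 <- assemble(list(good), order = "SCL")
  expect_equal(attr(determine_layer_order(net1, ann), "order"), "SCL")
})

test_that("per-layer annotation bookkeeping reports percentages of annotated proteins", {
  fx <- fig5_fixture()
  stats <- layer_annotation_stats(fx$net, fx$ann)
  scl <- stats[stats$layer == "SCL", ]
  expect_equal(scl$n_with_neighbors, 2L)  # A and B
  expect_equal(scl$n_annotated, 1L)       # only B is annotated
  expect_equal(scl$pct_annotated, 50)
  expect_equal(annotated_proportion(3, 4), 75)
  expect_equal(annotated_proportion(0, 0), 0)
})
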