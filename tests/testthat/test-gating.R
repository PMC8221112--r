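# Threshold derivation, hierarchical gating and quantification.

syntheticCells <- function(int, extra = list()) {
  n <- length(int[[1]])
  cc <- data.frame(cell_id = seq_len(n), x_um = runif(n, 0, 100),
                   y_um = runif(n, 0, 100), volume_um2 = rep(28, n),
                   sphericity = rep(0.95, n))
  for (ch in names(int)) cc[[paste0("mean_", ch)]] <- int[[ch]]
  for (ch in names(extra)) cc[[ch]] <- extra[[ch]]
  new("CellTable", cells = cc)
}

test_that("a two-mode mixture yields a single cut strictly between the modes", {
  withr::with_seed(1, {
    x <- c(rlnorm(700, 1, 0.25), rlnorm(300, 4, 0.25))
  })
  cells <- syntheticCells(list(m = x))
  for (method in c("gmm", "kde", "cluster")) {
    thr <- deriveThresholds(cells, list(m = list(method = method, levels = 2)))
    cut <- thresholdCuts(thr)$m
    expect_length(cut, 1)
    expect_gt(cut, exp(1))
    expect_lt(cut, exp(4))
  }
})

test_that("fixed and quantile cuts are returned verbatim", {
  cells <- syntheticCells(list(m = runif(100, 0, 1000)))
  thr <- deriveThresholds(cells, list(m = list(method = "fixed",
                                               cuts = c(10, 100))))
  expect_identical(thresholdCuts(thr)$m, c(10, 100))
  thrq <- deriveThresholds(cells, list(
    m = list(method = "quantile", probs = c(0.5))))
  expect_equal(thresholdCuts(thrq)$m,
               quantile(cellData(cells)$mean_m, 0.5, names = FALSE))
})

test_that("degenerate channels and small tables are rejected", {
  cells <- syntheticCells(list(m = rep(5, 100)))
  expect_error(deriveThresholds(cells, list(m = list(method = "gmm"))),
               "fixed")
  few <- syntheticCells(list(m = runif(10)))
  expect_error(deriveThresholds(few, list(m = list(method = "gmm"))),
               ">= 50")
})

test_that("the background rule isolates a rare positive mode", {
  withr::with_seed(2, {
    x <- c(rlnorm(2000, 1.2, 0.15), rlnorm(8, 5.5, 0.2))
  })
  cells <- syntheticCells(list(m = x))
  thr <- deriveThresholds(cells, list(m = list(method = "background",
                                               levels = 2, k = 8)))
  cut <- thresholdCuts(thr)$m
  pos <- x > cut
  expect_identical(sum(pos[1:2000]), 0L)
  expect_identical(sum(pos[2001:2008]), 8L)
})

test_that("three-level derivation recovers the generator's expression modes", {
  fx <- follicleFixture()
  tc <- groundTruthCells(fx$gt)
  # oracle: true expression draws carry the neg/dim/hi mode identity
  x <- tc$expr_CD20
  lab <- ifelse(x <= 0, "lo", ifelse(tc$phenotype %in% c("B_MZ", "B_DZ"),
                                     "dim", "hi"))
  cells <- syntheticCells(list(CD20 = x + rlnorm(length(x), 0, 0.1)))
  thr <- deriveThresholds(cells, list(CD20 = list(method = "kde",
                                                  levels = 3)))
  cuts <- thresholdCuts(thr)$CD20
  expect_length(cuts, 2)
  called <- ifelse(cells@cells$mean_CD20 > cuts[2], "hi",
                   ifelse(cells@cells$mean_CD20 > cuts[1], "dim", "lo"))
  expect_gte(mean(called == lab), 0.95)
})

test_that("gate trees validate their structure", {
  expect_error(gateTree("bad", list(a = list(parent = ""),
                                    b = list(parent = "zzz"))),
               "unknown parent")
  expect_error(gateTree("bad", list(a = list(parent = ""),
                                    b = list(parent = "a",
                                             channels = c(m = "++")))),
               "invalid level")
  tr <- backboneTree()
  expect_identical(unname(gatePaths(tr)["CD4T"]), "all/CD4T")
})

test_that("gating annotates cells per the ancestor predicate chain", {
  cells <- syntheticCells(list(CD20 = c(500, 500, 2, 2),
                               CD4 = c(3, 3, 400, 2)))
  thr <- thresholdSet(list(CD20 = 50, CD4 = 50))
  g <- cellData(applyGates(cells, backboneTree(), thr))
  expect_true(all(g$gate_all))
  expect_identical(g$gate_B, c(TRUE, TRUE, FALSE, FALSE))
  expect_identical(g$gate_CD4T, c(FALSE, FALSE, TRUE, FALSE))
  # root-only tree annotates everything with the root alone
  root <- gateTree("r", list(all = list(parent = "")))
  g2 <- cellData(applyGates(cells, root, thr))
  expect_true(all(g2$gate_all))
})

test_that("sibling +/- gates partition their parent exactly", {
  withr::with_seed(3, {
    n <- 400
    cells <- syntheticCells(list(CD4 = rlnorm(n, 4, 1),
                                 CD57 = rlnorm(n, 2, 1.5)))
  })
  tree <- gateTree("t", list(
    all = list(parent = ""),
    T4 = list(parent = "all", channels = c(CD4 = "+")),
    T4_57pos = list(parent = "T4", channels = c(CD57 = "+")),
    T4_57neg = list(parent = "T4", channels = c(CD57 = "-"))))
  thr <- thresholdSet(list(CD4 = 30, CD57 = 12))
  g <- cellData(applyGates(cells, tree, thr))
  expect_identical(sum(g$gate_T4_57pos) + sum(g$gate_T4_57neg),
                   sum(g$gate_T4))
  expect_identical(sum(g$gate_T4_57pos & g$gate_T4_57neg), 0L)
})

test_that("feature terms gate on event-table columns", {
  cells <- syntheticCells(list(m = c(100, 100, 100, 100)))
  cells@cells$volume_um2 <- c(40, 10, 30, 45)
  tree <- gateTree("t", list(
    all = list(parent = ""),
    big = list(parent = "all", channels = c(m = "+"),
               features = list(list(column = "volume_um2", op = ">=",
                                    value = "median")))))
  g <- cellData(applyGates(cells, tree, thresholdSet(list(m = 50))))
  # median volume = 35; cells 1 and 3? cell 3 is below 35
  expect_identical(g$gate_big, c(TRUE, FALSE, FALSE, TRUE))
  bad <- gateTree("t", list(
    all = list(parent = ""),
    x = list(parent = "all",
             features = list(list(column = "nope", op = ">", value = 1)))))
  expect_error(applyGates(cells, bad, thresholdSet(list(m = 50))), "nope")
})

test_that("gate labels agree with the generator phenotypes at default optics", {
  fx <- follicleFixture()
  thr <- deriveThresholds(fx$cells, backboneThresholdSpec())
  g <- cellData(applyGates(fx$cells, backboneTree(), thr))
  idx <- matchTruth(fx$cells, fx$gt)
  truth <- groundTruthCells(fx$gt)$phenotype[idx]
  predicted <- ifelse(g$gate_B, "B", ifelse(g$gate_CD4T, "T", "other"))
  expected <- ifelse(grepl("^B_", truth), "B",
                     ifelse(truth == "T", "T", "other"))
  expect_gte(mean(predicted == expected), 0.9)
})

test_that("quantification arithmetic and denominators behave as specified", {
  withr::with_seed(4, {
    cc <- data.frame(cell_id = 1:100, x_um = runif(100), y_um = runif(100),
                     volume_um2 = 28, sphericity = 0.9,
                     region = rep("LZ", 100), follicle_id = 1L,
                     tzone = FALSE,
                     gate_all = TRUE,
                     gate_B = c(rep(TRUE, 83), rep(FALSE, 17)),
                     gate_rare = FALSE)
  })
  cells <- new("CellTable", cells = cc,
               provenance = list(gate_parents = c(all = "", B = "all",
                                                  rare = "all")))
  q <- quantifyPopulations(cells, list(
    list(population = "B", scope = "GC", denominator = "total"),
    list(population = "rare", scope = "EF", denominator = "total"),
    list(population = "B", scope = "per-follicle", denominator = "total")),
    tissueAreaUm2 = 2e6)
  expect_equal(q$frequency_pct[1], 83)
  expect_equal(q$density_per_mm2[1], 83 / 2)
  expect_true(is.na(q$frequency_pct[2]))        # zero denominator -> missing
  expect_equal(q$frequency_pct[q$scope == "per-follicle"], 83)
})

test_that("child frequencies never exceed their parent in any scope", {
  fx <- cached("gcPipeline", function()
    runPipeline(referenceScene("gc_reference", seed = 2), "gc_reactivity"))
  g <- cellData(fx$cells)
  parents <- provenance(fx$cells)$gate_parents
  for (node in names(parents)) {
    p <- parents[[node]]
    if (identical(p, "")) next
    for (scope in c("EF", "F", "GC")) {
      m <- HistoCyto:::.scopeMask(g, scope)
      expect_lte(sum(g[[paste0("gate_", node)]][m]),
                 sum(g[[paste0("gate_", p)]][m]))
    }
  }
})
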