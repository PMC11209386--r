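test_that("confusion counting partitions the field of view", {
  set.seed(1)
  for (trial in 1:5) {
    gt <- matrix(rbinom(400, 1, 0.3), 20, 20)
    pred <- matrix(rbinom(400, 1, 0.3), 20, 20)
    fov <- matrix(rbinom(400, 1, 0.8), 20, 20)
    cc <- confusion(pred, gt, fov)
    expect_identical(cc$tp + cc$fp + cc$tn + cc$fn, sum(fov))
  }
  gt <- matrix(rbinom(100, 1, 0.4), 10, 10)
  fov <- matrix(1L, 10, 10)
  perfect <- confusion(gt, gt, fov)
  expect_identical(perfect$fp + perfect$fn, 0L)
  flipped <- confusion(1 - gt, gt, fov)
  expect_identical(flipped$tp + flipped$tn, 0L)
  expect_error(confusion(gt, matrix(0, 5, 5)), "geometry")
})

test_that("metric scores equal hand-computed ratios", {
  r <- metrics(list(tp = 3, fp = 1, tn = 94, fn = 2))
  expect_equal(r$iou, 0.5)
  expect_equal(r$sen, 0.6)
  expect_equal(r$spe, 94 / 95)
  expect_equal(r$acc, 0.97)
  expect_equal(r$f1, 2 / 3)
  perfect <- metrics(list(tp = 50, fp = 0, tn = 50, fn = 0))
  for (k in c("iou", "acc", "sen", "spe", "f1")) expect_equal(perfect[[k]], 1)
})

test_that("the F1/IOU identity holds for arbitrary counts", {
  set.seed(2)
  for (trial in 1:50) {
    cc <- list(tp = sample(0:50, 1) + 1, fp = sample(0:50, 1),
               tn = sample(0:50, 1), fn = sample(0:50, 1))
    r <- metrics(cc)
    d <- metrics_direct(cc$tp, cc$fp, cc$tn, cc$fn)
    expect_equal(r$f1, f1_from_iou(r$iou), tolerance = 1e-12)
    for (k in names(d)) expect_equal(r[[k]], d[[k]], tolerance = 1e-12)
  }
})

test_that("sensitivity and specificity depend only on their own classes", {
  set.seed(3)
  for (trial in 1:20) {
    base <- list(tp = sample(1:50, 1), fp = sample(1:50, 1),
                 tn = sample(1:50, 1), fn = sample(1:50, 1))
    jig <- base
    jig$tn <- base$tn + 13; jig$fp <- base$fp  # Sen blind to TN
    expect_equal(metrics(jig)$sen, metrics(base)$sen)
    jig <- base
    jig$tp <- base$tp + 7; jig$fn <- base$fn   # Spe blind to TP
    expect_equal(metrics(jig)$spe, metrics(base)$spe)
  }
})

test_that("swapping prediction and truth exchanges recall with precision", {
  set.seed(4)
  gt <- matrix(rbinom(400, 1, 0.3), 20, 20)
  pred <- matrix(rbinom(400, 1, 0.35), 20, 20)
  a <- confusion(pred, gt)
  b <- confusion(gt, pred)
  ma <- metrics(a); mb <- metrics(b)
  precision_a <- a$tp / (a$tp + a$fp)
  expect_equal(mb$sen, precision_a)
  expect_equal(ma$acc, mb$acc)
})

test_that("pooled aggregation equals evaluation of concatenated masks", {
  set.seed(5)
  gt1 <- matrix(rbinom(64, 1, 0.5), 8, 8); p1 <- matrix(rbinom(64, 1, 0.5), 8, 8)
  gt2 <- matrix(rbinom(400, 1, 0.05), 20, 20); p2 <- matrix(0L, 20, 20)
  r1 <- metrics(confusion(p1, gt1)); r2 <- metrics(confusion(p2, gt2))
  pooled <- aggregate_reports(list(r1, r2), mode = "pooled")
  concat_counts <- confusion(rbind(matrix(p1, 64, 1), matrix(p2, 400, 1)),
                             rbind(matrix(gt1, 64, 1), matrix(gt2, 400, 1)))
  direct <- metrics(concat_counts)
  for (k in c("iou", "acc", "sen", "spe", "f1"))
    expect_equal(pooled[[k]], direct[[k]], tolerance = 1e-12)
  avg <- aggregate_reports(list(r1, r2), mode = "mean")
  expect_false(isTRUE(all.equal(pooled$acc, avg$acc)))
  expect_identical(attr(pooled, "mode"), "pooled")
  # single report and identical pairs are fixed points of both modes
  for (mode in c("pooled", "mean")) {
    one <- aggregate_reports(list(r1), mode = mode)
    two <- aggregate_reports(list(r1, r1), mode = mode)
    for (k in c("iou", "acc", "sen", "spe", "f1")) {
      expect_equal(one[[k]], r1[[k]], tolerance = 1e-12)
      expect_equal(two[[k]], r1[[k]], tolerance = 1e-12)
    }
  }
  expect_error(aggregate_reports(list()), "no reports")
})

test_that("report deltas are percentage points rounded for display", {
  a <- list(acc = 0.9570, sen = 0.8147, spe = 0.9776, f1 = 0.8271, iou = 0.7052)
  expect_true(all(compare_reports(a, a) == 0))
  b <- list(acc = 0.9554, sen = 0.7435, spe = 0.9860, f1 = 0.8078, iou = 0.6776)
  expect_equal(unname(compare_reports(a, b)["sen"]), 7.12)
})

test_that("vacuous denominators return one with a message", {
  expect_message(r <- metrics(list(tp = 0, fp = 0, tn = 10, fn = 0)), "Sen")
  expect_equal(r$sen, 1)
  expect_equal(r$iou, 1)
  expect_equal(r$acc, 1)
  expect_error(metrics(list(tp = 0, fp = 0, tn = 0, fn = 0)), "empty")
})

test_that("reports are written with the table column order", {
  set.seed(6)
  gt <- matrix(rbinom(64, 1, 0.3), 8, 8)
  r <- metrics(confusion(gt, gt))
  ev <- list(aggregate = r,
             per_image = data.frame(id = "s1", as.data.frame(r)))
  csv <- tempfile(fileext = ".csv"); js <- tempfile(fileext = ".json")
  tab <- write_report(ev, csv = csv, json = js)
  expect_identical(names(tab), c("id", "acc", "sen", "spe", "f1", "iou"))
  expect_identical(tab$id[nrow(tab)], "aggregate")
  expect_true(file.exists(csv) && file.exists(js))
  back <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(back$acc, tab$acc)
  unlink(c(csv, js))
})
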