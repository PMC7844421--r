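# Ensemble difference distance matrix machinery.

test_that("constant geometry gives constant distances", {
  co <- array(0, c(5, 2, 3))
  co[, 2, 1] <- 5
  ens <- structure(list(coords = co, residue_labels = c("R1", "R2"),
                        state_label = "A"), class = "ensemble")
  de <- residue_distance_ensemble(ens)
  expect_true(all(de$distances == 5))
})

test_that("distances are invariant under rigid motions", {
  ep <- simulate_ensemble_pair(n_res = 8, n_conf = 12, fluct_sd = 0.2,
                               seed = 2)
  de <- residue_distance_ensemble(ep$a)
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  co2 <- ep$a$coords
  for (m in seq_len(dim(co2)[1])) {
    co2[m, , ] <- co2[m, , ] %*% R + rep(c(10, -4, 2), each = dim(co2)[2])
  }
  ens2 <- structure(list(coords = co2, residue_labels = ep$a$residue_labels,
                         state_label = "A"), class = "ensemble")
  de2 <- residue_distance_ensemble(ens2)
  expect_equal(de2$distances, de$distances, tolerance = 1e-9)
})

test_that("distances equal a naive double-loop computation", {
  ep <- simulate_ensemble_pair(n_res = 10, n_conf = 11, fluct_sd = 0.4,
                               seed = 3)
  de <- residue_distance_ensemble(ep$a)
  co <- ep$a$coords
  for (k in sample(nrow(de$pair_index), 12)) {
    i <- de$pair_index$i[k]; j <- de$pair_index$j[k]
    ref <- vapply(seq_len(dim(co)[1]), function(m) {
      sqrt(sum((co[m, i, ] - co[m, j, ])^2))
    }, numeric(1))
    expect_equal(de$distances[, k], ref, tolerance = 1e-12)
  }
})

test_that("masking caps distances and saturates differences", {
  co <- array(0, c(3, 3, 3))
  co[, 2, 1] <- c(5, 5, 5); co[, 3, 1] <- c(15, 25, 20)
  ens <- structure(list(coords = co, residue_labels = paste0("R", 1:3),
                        state_label = "A"), class = "ensemble")
  de <- mask_distances(residue_distance_ensemble(ens), cap = 10)
  expect_equal(sort(unique(as.numeric(de$distances))), c(5, 10))
  # all distances < cap: identity
  de2 <- residue_distance_ensemble(ens)
  de3 <- mask_distances(de2, cap = 100)
  expect_equal(de3$distances, de2$distances)
})

test_that("pairs beyond the cap in both states are never significant", {
  ep <- simulate_ensemble_pair(n_res = 12, n_conf = 60,
                               shifts = data.frame(i = 1, j = 12, delta = 3),
                               fluct_sd = 0.2, seed = 4)
  da <- residue_distance_ensemble(ep$a)
  k <- which(da$pair_index$i == 1 & da$pair_index$j == 12)
  if (min(da$distances[, k]) > 10) {
    r <- eddm_compare(ep$a, ep$b, cap = 10)
    expect_equal(r$mean_diff[r$i == 1 & r$j == 12], 0)
  } else succeed()
})

test_that("state exchange negates mean differences and keeps p-values", {
  ep <- simulate_ensemble_pair(n_res = 10, n_conf = 80,
                               shifts = data.frame(i = 2, j = 4, delta = 1.5),
                               fluct_sd = 0.3, seed = 5)
  r1 <- eddm_compare(ep$a, ep$b)
  r2 <- eddm_compare(ep$b, ep$a)
  expect_equal(r2$mean_diff, -r1$mean_diff, tolerance = 1e-12)
  expect_equal(r2$p, r1$p, tolerance = 1e-9)
})

test_that("decreasing the cap never increases |mean_diff| of shifted pairs", {
  ep <- simulate_ensemble_pair(n_res = 10, n_conf = 50,
                               shifts = data.frame(i = 2, j = 4, delta = 2),
                               fluct_sd = 0.4, seed = 6)
  r10 <- eddm_compare(ep$a, ep$b, cap = 10)
  r6 <- eddm_compare(ep$a, ep$b, cap = 6)
  # exact monotonicity holds where one state stochastically dominates
  # (the shifted pairs); null pairs fluctuate within sampling noise
  shifted <- abs(r10$mean_diff) > 0.2
  expect_true(any(shifted))
  expect_true(all(abs(r6$mean_diff[shifted]) <=
                    abs(r10$mean_diff[shifted]) + 1e-9))
  expect_lt(max(abs(r6$mean_diff[!shifted]) - abs(r10$mean_diff[!shifted])),
            0.05)
})

test_that("an injected shift flags that pair (and only pairs with residue j)", {
  ep <- simulate_ensemble_pair(n_res = 14, n_conf = 400,
                               shifts = data.frame(i = 4, j = 6, delta = 2),
                               fluct_sd = 0.3, seed = 7)
  r <- eddm_compare(ep$a, ep$b)
  sig <- r[r$significant, , drop = FALSE]
  expect_true(any(sig$i == 4 & sig$j == 6))
  expect_true(all(sig$i == 6 | sig$j == 6))
})

test_that("mismatched residue sets are rejected", {
  a <- simulate_ensemble_pair(n_res = 8, n_conf = 40, seed = 8)$a
  b <- simulate_ensemble_pair(n_res = 9, n_conf = 40, seed = 9)$a
  expect_error(eddm_compare(a, b), "mismatch")
})

test_that("multi-model PDB round trip preserves coordinates", {
  ep <- simulate_ensemble_pair(n_res = 6, n_conf = 12, fluct_sd = 0.3,
                               seed = 10)
  f <- tempfile(fileext = ".pdb")
  write_ensemble_pdb(ep$a, f)
  back <- read_ensemble_pdb(f)
  expect_equal(dim(back$coords), dim(ep$a$coords))
  expect_equal(back$coords, ep$a$coords, tolerance = 5e-4)  # 3-decimal PDB
})

test_that("annotation joins structural elements onto pairs", {
  ep <- simulate_ensemble_pair(n_res = 10, n_conf = 40, seed = 11)
  r <- eddm_compare(ep$a, ep$b)
  ann <- tibble::tibble(element = c("beta9", "alpha4"),
                        from = c(1, 6), to = c(5, 10))
  ra <- eddm_annotate(r, ann)
  expect_equal(ra$element_i[ra$i == 2][1], "beta9")
  expect_equal(ra$element_j[ra$j == 8][1], "alpha4")
  m <- eddm_matrix(r)
  expect_true(isSymmetric(m))
})
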