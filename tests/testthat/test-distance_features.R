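test_that("model distance map matches Euclidean geometry", {
  # 3-4-5 triangle
  m <- model_distance_map(rbind(c(0, 0, 0), c(3, 4, 0)))
  expect_equal(m$values, matrix(c(0, 5, 5, 0), 2, 2))
  expect_identical(m$source, "model")

  # tabulated 5-residue chain vs brute-force all-pairs oracle
  coords <- rbind(c(0, 0, 0), c(3.8, 0, 0), c(5.1, 3.2, 1.0),
                  c(2.2, 6.0, 0.5), c(-1.4, 4.9, 2.2))
  m5 <- model_distance_map(coords)
  expect_identical(m5$values, bf_dist_matrix(coords))

  # symmetry and zero diagonal by construction on a random model
  set.seed(41)
  mr <- model_distance_map(matrix(rnorm(30, sd = 8), 10, 3))
  expect_identical(mr$values, t(mr$values))
  expect_true(all(diag(mr$values) == 0))

  expect_error(model_distance_map(matrix(0, 1, 3)), "degenerate")
})

test_that("PDB parsing follows the representative-atom convention", {
  ca <- rbind(c(0, 0, 0), c(3.8, 0, 0), c(7.6, 0, 0))
  cb <- ca + matrix(rep(c(0, 1.53, 0), each = 3), 3, 3)
  pdb <- write_test_pdb(tempfile(fileext = ".pdb"), ca, cb,
                        resid = c("ALA", "GLY", "ALA"))
  m <- model_distance_map(pdb)
  # representative atoms: CB, CA (gly fallback), CB
  rep_xyz <- rbind(cb[1, ], ca[2, ], cb[3, ])
  expect_equal(m$values, bf_dist_matrix(rep_xyz), tolerance = 1e-3)
  expect_identical(attr(m, "atom"), "cb")

  # forced C-alpha convention
  mca <- model_distance_map(pdb, atom = "ca")
  expect_equal(mca$values, bf_dist_matrix(ca), tolerance = 1e-3)

  # missing residue: rows set above any threshold, with a warning
  pdb_gap <- write_test_pdb(tempfile(fileext = ".pdb"), ca[c(1, 3), ],
                            resno = c(1, 3))
  expect_warning(mg <- model_distance_map(pdb_gap, length = 3), "missing")
  expect_identical(mg$length, 3L)
  expect_true(all(is.infinite(mg$values[2, -2])))
  expect_identical(mg$values[2, 2], 0)

  # malformed coordinate field is reported with its line number
  bad <- tempfile(fileext = ".pdb")
  lines <- readLines(pdb)
  substr(lines[2], 31, 38) <- "  xx.xxx"
  writeLines(lines, bad)
  expect_error(model_distance_map(bad), "line 2")
})

test_that("predicted-map reader validates, symmetrizes and errors precisely", {
  m <- random_sym_map(3, max_d = 12)
  f <- write_map_file(tempfile(), m)
  got <- read_predicted_map(f, expected_length = 3)
  expect_equal(got$values, m, tolerance = 1e-7)
  expect_identical(got$source, "predicted")

  # mild asymmetry is averaged
  ma <- m
  ma[1, 2] <- 8.0
  ma[2, 1] <- 8.2
  got2 <- read_predicted_map(write_map_file(tempfile(), ma))
  expect_equal(got2$values[1, 2], 8.1, tolerance = 1e-7)
  expect_equal(got2$values[2, 1], 8.1, tolerance = 1e-7)

  # asymmetry beyond tolerance is a corrupt file
  mb <- m
  mb[1, 3] <- 2
  mb[3, 1] <- 4
  expect_error(read_predicted_map(write_map_file(tempfile(), mb)),
               "asymmetric")

  # shape and parse errors carry positions
  f45 <- tempfile()
  writeLines(c("1 2 3 4 5", "1 2 3 4 5", "1 2 3 4 5", "1 2 3 4 5"), f45)
  expect_error(read_predicted_map(f45, expected_length = 4), "dimension")
  fbad <- tempfile()
  writeLines(c("0 1 2", "1 0 oops", "2 3 0"), fbad)
  expect_error(read_predicted_map(fbad), "row 2, column 3")
})

test_that("mutual threshold filter zeroes both maps and is idempotent", {
  # if either entry exceeds the cutoff, both are zeroed
  a <- random_sym_map(4, max_d = 14)
  b <- random_sym_map(4, max_d = 14)
  a[1, 3] <- a[3, 1] <- 20
  b[1, 3] <- b[3, 1] <- 10
  fp <- apply_threshold_filter(a, b, threshold = 16)
  expect_identical(fp$a_star[1, 3], 0)
  expect_identical(fp$b_star[1, 3], 0)

  # identity below the cutoff
  a2 <- random_sym_map(5, max_d = 15)
  b2 <- random_sym_map(5, max_d = 15)
  fp2 <- apply_threshold_filter(a2, b2, threshold = 16)
  expect_identical(fp2$a_star, a2)
  expect_identical(fp2$b_star, b2)

  # random pairs match a per-entry oracle, and refiltering changes nothing
  set.seed(7)
  for (rep in 1:5) {
    a3 <- random_sym_map(6)
    b3 <- random_sym_map(6)
    fp3 <- apply_threshold_filter(a3, b3, 16)
    oracle_a <- a3
    oracle_b <- b3
    for (i in 1:6) {
      for (j in 1:6) {
        if (a3[i, j] > 16 || b3[i, j] > 16) {
          oracle_a[i, j] <- 0
          oracle_b[i, j] <- 0
        }
      }
    }
    expect_identical(fp3$a_star, oracle_a)
    expect_identical(fp3$b_star, oracle_b)
    again <- apply_threshold_filter(fp3$a_star, fp3$b_star, 16)
    expect_identical(again$a_star, fp3$a_star)
    expect_identical(again$b_star, fp3$b_star)
  }

  expect_error(apply_threshold_filter(random_sym_map(4), random_sym_map(5)),
               "dimension")
})

test_that("difference map is the upper-triangular filtered residual", {
  a <- random_sym_map(3, max_d = 10)
  fp_same <- apply_threshold_filter(a, a, 16)
  expect_true(all(difference_map(fp_same)$values == 0))

  a2 <- matrix(0, 3, 3)
  b2 <- matrix(0, 3, 3)
  a2[1, 2] <- a2[2, 1] <- 5
  b2[1, 2] <- b2[2, 1] <- 6
  u <- difference_map(apply_threshold_filter(a2, b2, 16))
  expect_identical(u$values[1, 2], -1)
  expect_identical(u$values[2, 1], 0)
  expect_identical(sum(u$values != 0), 1L)

  # strictly-lower triangle and diagonal exactly zero, antisymmetry of roles
  set.seed(11)
  for (rep in 1:5) {
    x <- random_sym_map(7)
    y <- random_sym_map(7)
    uxy <- difference_map(apply_threshold_filter(x, y, 16))$values
    uyx <- difference_map(apply_threshold_filter(y, x, 16))$values
    expect_true(all(uxy[lower.tri(uxy, diag = TRUE)] == 0))
    expect_identical(uxy[upper.tri(uxy)], -uyx[upper.tri(uyx)])
    # nonzero entries only where both maps are under the cutoff
    nz <- which(uxy != 0, arr.ind = TRUE)
    if (nrow(nz) > 0) {
      expect_true(all(nz[, 1] < nz[, 2]))
      expect_true(all(x[nz] <= 16 & y[nz] <= 16))
    }
  }
})

test_that("featurize_model composes the pipeline deterministically", {
  set.seed(23)
  ca <- generate_chain(10, seed = 23)
  cb <- ca + matrix(rep(c(0, 0, 1.53), each = 10), 10, 3)
  pdb <- write_test_pdb(tempfile(fileext = ".pdb"), ca, cb)
  # predicted map == model map: a perfect model gives an all-zero input
  bmap <- model_distance_map(pdb)
  rec <- featurize_model(pdb, distance_map(bmap$values),
                         target_id = "T1", model_id = "m1")
  expect_true(all(rec$diff$values == 0))

  # equals composing the three operations manually
  pm <- random_sym_map(10, max_d = 25)
  fpm <- write_map_file(tempfile(), pm)
  rec2 <- featurize_model(pdb, fpm, threshold = 16)
  amap <- read_predicted_map(fpm)
  manual <- difference_map(apply_threshold_filter(amap, bmap, 16))
  expect_identical(rec2$diff$values, manual$values)

  # bit-identical on repeat
  rec3 <- featurize_model(pdb, fpm, threshold = 16)
  expect_identical(rec2$diff$values, rec3$diff$values)

  # model shorter than the predicted map: featurization still aligns by
  # residue number; a 9-residue model against a 10 x 10 map flags residue 10
  pdb9 <- write_test_pdb(tempfile(fileext = ".pdb"), ca[1:9, ], cb[1:9, ])
  expect_warning(rec9 <- featurize_model(pdb9, fpm), "missing")
  expect_identical(rec9$length, 10L)
  # a map smaller than the model cannot align
  f6 <- write_map_file(tempfile(), random_sym_map(6))
  expect_error(featurize_model(pdb, f6), "1..6")
})

test_that("feature store and manifest round-trip", {
  recs <- random_records(6, lengths = c(9, 12), seed = 3)
  store_path <- tempfile(fileext = ".rds")
  write_feature_store(recs, store_path, threshold = 16, atom = "cb")
  store <- read_feature_store(store_path)
  expect_identical(store$threshold, 16)
  back <- dmqa:::store_records(store)
  expect_identical(length(back), 6L)
  expect_identical(back[[3]]$diff$values, recs[[3]]$diff$values)
  expect_identical(back[[3]]$target_id, recs[[3]]$target_id)

  man_path <- tempfile(fileext = ".tsv")
  recs[[2]]$true_gdtts <- NA_real_
  write_feature_manifest(recs, man_path)
  man <- read.table(man_path, header = TRUE, sep = "\t",
                    colClasses = "character")
  expect_identical(names(man),
                   c("target_id", "model_id", "length", "feature_key",
                     "true_gdtts"))
  expect_identical(man$true_gdtts[2], "")
  expect_identical(man$feature_key[1],
                   paste(recs[[1]]$target_id, recs[[1]]$model_id, sep = "/"))
})
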