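random_points <- function(n, spread = 10) {
  matrix(stats::rnorm(3 * n, 0, spread), ncol = 3)
}

random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(w*w + x*x - y*y - z*z, 2*(x*y - w*z), 2*(x*z + w*y),
           2*(x*y + w*z), w*w - x*x + y*y - z*z, 2*(y*z - w*x),
           2*(x*z - w*y), 2*(y*z + w*x), w*w - x*x - y*y + z*z),
         nrow = 3, byrow = TRUE)
}

test_that("Kabsch agrees with the quaternion reference on random sets", {
  set.seed(19)
  for (k in 1:200) {
    n <- sample(4:40, 1)
    P <- random_points(n)
    Q <- random_points(n)
    a <- kabsch(P, Q)
    b <- kabsch_horn(P, Q)
    expect_lt(abs(a$rmsd - b$rmsd), 1e-9)
    expect_lt(max(abs(a$rotation - b$rotation)), 1e-6)
    expect_lt(abs(det(a$rotation) - 1), 1e-9) # proper rotation, never a mirror
  }
})

test_that("rmsd is rigid-motion invariant, symmetric and exact on copies", {
  set.seed(23)
  P <- random_points(25)
  expect_lt(kabsch(P, P)$rmsd, 1e-12)
  for (k in 1:50) {
    R <- random_rotation()
    t <- stats::rnorm(3, 0, 50)
    Q <- P %*% t(R) + matrix(t, 25, 3, byrow = TRUE)
    expect_lt(kabsch(P, Q)$rmsd, 1e-9)
    # perturbed copy: rmsd symmetric under argument swap
    Q2 <- Q + matrix(stats::rnorm(75, 0, 0.5), 25, 3)
    expect_lt(abs(kabsch(P, Q2)$rmsd - kabsch(Q2, P)$rmsd), 1e-9)
  }
})

test_that("degenerate coordinate sets are rejected", {
  line <- cbind(1:10, 2 * (1:10), 3 * (1:10))
  expect_error(kabsch(line, line + 1), "degenerate")
  expect_error(kabsch(cbind(1, 1, 1), cbind(2, 2, 2)), "at least 3")
})

test_that("pairing intersects UniProt numbering order-preservingly", {
  a <- as_coordinate_set("P1", 1:100, random_points(100))
  b <- as_coordinate_set("P1", 50:150, random_points(101))
  pq <- pair_by_unp(a, b)
  expect_equal(pq$unp_num, 50:100)
  expect_equal(nrow(pq$P), 51L)
  # identical sets pair fully
  full <- pair_by_unp(a, a)
  expect_equal(nrow(full$P), 100L)
  # disjoint coverage errors out
  c2 <- as_coordinate_set("P1", 200:260, random_points(61))
  expect_error(pair_by_unp(a, c2), "insufficient overlap")
  expect_error(pair_by_unp(a, as_coordinate_set("P2", 1:50,
                                                random_points(50))),
               "different accessions")
})

test_that("multi-structure superposition averages pairwise rmsds", {
  set.seed(31)
  base <- random_points(60)
  copy <- function() {
    R <- random_rotation()
    as_coordinate_set("P1", 1:60,
                      base %*% t(R) + matrix(stats::rnorm(3, 0, 20), 60, 3,
                                             byrow = TRUE))
  }
  # identical sets (up to rigid motion) -> average 0
  res <- multi_superpose(list(copy(), copy(), copy()))
  expect_lt(res$average_rmsd, 1e-9)
  expect_equal(nrow(res$pairs), 3L)
  # to_first averaging uses K-1 pairs
  res2 <- multi_superpose(list(copy(), copy(), copy(), copy()),
                          method = "to_first")
  expect_equal(nrow(res2$pairs), 3L)
  expect_true(all(res2$pairs$i == 1L))
  # a failing pair is excluded with a warning, the rest still averages
  sets <- list(copy(), copy(),
               as_coordinate_set("P1", 200:260, random_points(61)))
  expect_warning(res3 <- multi_superpose(sets), "excluded")
  expect_equal(nrow(res3$pairs), 1L)
})

test_that("coordinate sets read back from augmented files superpose", {
  d <- tempfile(); dir.create(d); on.exit(unlink(d, recursive = TRUE))
  fx <- fixture_preset("tag", seed = 8, dir = d)
  cfg <- run_config(cif = fx$cif, uniprot_fasta = attr(fx$records, "fasta"),
                    uniprot_meta = attr(fx$records, "meta"),
                    curated = fx$curated, taxonomy = attr(fx$tree, "path"),
                    domains = fx$domains, out_dir = d)
  rep <- suppressMessages(suppressWarnings(run_augment(cfg)))
  acc <- fx$truth$expected_best[1]
  cs <- coordinate_set(rep$output[1], acc)
  expect_s3_class(cs, "coordinate_set")
  expect_true(all(diff(cs$unp_num) > 0))
  expect_gte(nrow(cs$xyz), 3L)
  # a structure is at zero rmsd from itself through the full file path
  res <- multi_superpose(list(cs, cs))
  expect_lt(res$average_rmsd, 1e-12)
})
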