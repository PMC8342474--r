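test_that("sequency Walsh matrices have sorted sign changes and are orthogonal", {
  expect_identical(walsh_sequency_matrix(0), matrix(1L, 1, 1))
  expect_identical(walsh_sequency_matrix(1),
                   matrix(c(1L, 1L, 1L, -1L), 2, 2, byrow = TRUE))
  # frozen by the sequency definition: rows with 0, 1, 2, 3 sign changes
  expect_identical(
    walsh_sequency_matrix(2),
    matrix(c(1, 1, 1, 1,
             1, 1, -1, -1,
             1, -1, -1, 1,
             1, -1, 1, -1), 4, 4, byrow = TRUE, dimnames = NULL) |>
      (\(m) {storage.mode(m) <- "integer"; m})()
  )
  for (m in 1:4) {
    W <- walsh_sequency_matrix(m)
    n <- 2^m
    expect_equal(apply(W, 1, count_sign_changes), 0:(n - 1))
    expect_equal(W %*% t(W), n * diag(n))
    expect_equal(W, t(W)) # symmetry underpins the self-inverse transform
  }
  expect_error(walsh_sequency_matrix(-1), class = "holopix_invalid")
})

test_that("basis patterns are outer products with the binary/bipolar identity", {
  plan <- hadamard_plan(4)
  # order 1 is all ones in both polarities
  expect_true(all(basis_pattern(plan, 1, "bipolar")$values == 1))
  expect_true(all(basis_pattern(plan, 1, "binary")$values == 1))
  # side 2, sequency pair (0, 1): outer product of rows (+1,+1) and (+1,-1)
  p2 <- hadamard_plan(2)
  n01 <- p2$order_lookup[0 + 1, 1 + 1]
  expect_equal(basis_pattern(p2, n01, "bipolar")$values,
               matrix(c(1, -1, 1, -1), 2, 2, byrow = TRUE))
  for (n in 2:plan$n_total) {
    bip <- basis_pattern(plan, n, "bipolar")$values
    bin <- basis_pattern(plan, n, "binary")$values
    expect_equal(bin, (bip + 1) / 2)
    expect_equal(sum(bin), plan$n_total / 2) # non-DC patterns are balanced
  }
  expect_error(basis_pattern(plan, 0), class = "holopix_invalid")
  expect_error(basis_pattern(plan, plan$n_total + 1), class = "holopix_invalid")
})

test_that("pattern orthogonality holds across the full basis on a small side", {
  plan <- hadamard_plan(4)
  pats <- lapply(seq_len(plan$n_total),
                 function(n) basis_pattern(plan, n, "bipolar")$values)
  G <- sapply(pats, function(a) sapply(pats, function(b) sum(a * b)))
  expect_equal(G, plan$n_total * diag(plan$n_total))
})

test_that("fwht2 matches its frozen examples and the brute-force projection", {
  p2 <- hadamard_plan(2)
  cf <- fwht2(matrix(c(1, 0, 0, 0), 2, 2) + 0i, p2)
  expect_equal(cf$value, rep(0.5 + 0i, 4)) # naive H X H / N oracle
  # uniform image: only the DC coefficient survives, a_1 = side * A
  s <- 8
  plan <- hadamard_plan(s)
  cfu <- fwht2(matrix(0.3 + 0i, s, s), plan)
  expect_equal(cfu$value[1], s * 0.3 + 0i)
  expect_equal(max(Mod(cfu$value[-1])), 0)
  # brute-force projection agreement for every order
  z <- as_complex_matrix(random_complex_image(8, seed = 42))
  cf8 <- fwht2(z, plan)
  oracle <- vapply(seq_len(plan$n_total), function(n) {
    sum(z * basis_pattern(plan, n, "bipolar")$values) / s
  }, complex(1))
  expect_lt(max(Mod(cf8$value - oracle)), 1e-12)
  expect_error(fwht2(z, hadamard_plan(4)), class = "holopix_invalid")
})

test_that("the transform is unitary: round trip and Parseval", {
  for (s in c(4, 16, 32)) {
    plan <- hadamard_plan(s)
    z <- as_complex_matrix(random_complex_image(s, seed = s))
    cf <- fwht2(z, plan)
    expect_lt(max(Mod(ifwht2(cf, plan) - z)), 1e-10)
    expect_lt(abs(sum(Mod(cf$value)^2) - sum(Mod(z)^2)) / sum(Mod(z)^2), 1e-9)
  }
})

test_that("missing orders are treated as exact zeros by ifwht2", {
  plan <- hadamard_plan(8)
  z <- as_complex_matrix(random_complex_image(8, seed = 5))
  cf <- fwht2(z, plan)
  kept <- cf[cf$order <= 10, ]
  zero_filled <- cf
  zero_filled$value[zero_filled$order > 10] <- 0 + 0i
  expect_equal(ifwht2(kept, plan), ifwht2(zero_filled, plan))
})

test_that("the square path visits shells of nondecreasing max(u, v)", {
  p2 <- hadamard_plan(2)
  expect_identical(square_path(p2), 1:4)
  expect_equal(p2$uv, cbind(c(0L, 0L, 1L, 1L), c(0L, 1L, 1L, 0L)))
  plan <- hadamard_plan(16)
  path <- square_path(plan)
  expect_identical(sort(path), 1:plan$n_total) # permutation
  expect_identical(path[1], 1L)
  shell <- pmax(plan$uv[path, 1], plan$uv[path, 2])
  expect_true(all(diff(shell) >= 0))
  # prefix at ratio sr only reaches pairs with max(u,v) <= ceil(side*sqrt(sr)) + 1
  for (sr in c(0.0625, 0.25, 0.5)) {
    keep <- path[seq_len(ceiling(sr * plan$n_total))]
    expect_lte(max(pmax(plan$uv[keep, 1], plan$uv[keep, 2])),
               ceiling(plan$side * sqrt(sr)) + 1)
  }
  expect_error(square_path(hadamard_plan(4, ordering = "natural")),
               class = "holopix_invalid")
})

test_that("plan validation rejects non-power-of-2 sides", {
  expect_error(hadamard_plan(3), class = "holopix_invalid")
  expect_error(hadamard_plan(0), class = "holopix_invalid")
})
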