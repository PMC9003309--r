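test_that("exponential/logarithm maps round-trip over random rotations", {
  set.seed(42)
  dirs <- matrix(rnorm(300), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  phi <- dirs * runif(100, 0, pi - 0.1)
  q <- quatExp(phi)
  expect_true(max(abs(rowSums(q^2) - 1)) < 1e-12)
  back <- quatLog(q)
  expect_true(max(abs(back - phi)) < 1e-9)
})

test_that("quaternion rotation agrees with matrix rotation", {
  set.seed(7)
  for (i in 1:20) {
    phi <- rnorm(3)
    v <- rnorm(3)
    expect_equal(quatRotate(quatExp(phi), v),
                 as.numeric(so3Exp(phi) %*% v), tolerance = 1e-12)
  }
})

test_that("quaternion multiplication matches rotation composition", {
  set.seed(8)
  a <- quatExp(rnorm(3)); b <- quatExp(rnorm(3))
  expect_equal(quatToMatrix(quatMult(a, b)),
               quatToMatrix(a) %*% quatToMatrix(b), tolerance = 1e-12)
  # batch path equals scalar path
  A <- quatExp(matrix(rnorm(30), ncol = 3))
  B <- quatExp(matrix(rnorm(30), ncol = 3))
  AB <- quatMult(A, B)
  for (i in 1:10)
    expect_equal(AB[i, ], quatMult(A[i, ], B[i, ]), tolerance = 1e-12)
})

test_that("matrixToQuat inverts quatToMatrix including near-pi rotations", {
  set.seed(9)
  for (ang in c(0.001, 1.5, pi - 0.001)) {
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
    q <- quatExp(ax * ang)
    q2 <- matrixToQuat(quatToMatrix(q))
    expect_lt(min(sum((q - q2)^2), sum((q + q2)^2)), 1e-18)
  }
})
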