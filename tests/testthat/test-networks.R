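test_that("component layer lists carry the exact parameter counts", {
  s1 <- buildSubnet1()
  expect_identical(countParameters(s1), 245792L)
  # layer-wise: 1216 + 4640 + 18496 + 73856 + 147584
  convs <- Filter(function(l) l$kind == "conv2d", s1@layers)
  expect_length(convs, 5L)
  expect_identical(vapply(convs, function(l) l$filters, integer(1)),
                   c(16L, 32L, 64L, 128L, 128L))
  expect_identical(countParameters(buildSubnet2()), 33281L)
  expect_identical(countParameters(buildAttentionModule()), 33281L)
  expect_identical(countParameters(buildResNet50Spec()), 23589761L)
})

test_that("assembled variants reproduce the published totals", {
  set.seed(1)
  expect_identical(countParameters(assembleModel("EMIL_A", 86)), 312354L)
  expect_identical(countParameters(assembleModel("EMIL_M", 86)), 279073L)
  expect_identical(countParameters(assembleModel("IMIL_A", 86)), 312354L)
  expect_identical(countParameters(assembleModel("IMIL_M", 86)), 279073L)
  expect_identical(countParameters(assembleModel("IMIL_SA", 86)), 312354L)
  # attention module accounts exactly for the difference
  expect_identical(312354 - 279073, 33281)
  # the count does not depend on the patch side (weight sharing + GAP)
  for (ps in c(86L, 129L, 172L, 258L, 344L))
    expect_identical(countParameters(assembleModel("IMIL_SA", ps)), 312354L)
  expect_error(assembleModel("IMIL_X", 86))
  expect_error(assembleModel("IMIL_A", 16), "at least 32")
})

test_that("encoder survives the smallest patch and always emits 128-d", {
  expect_identical(SparseMIL:::.subnet1SpatialTrace(86),
                   c(28L, 14L, 7L, 3L, 3L))
  set.seed(3)
  m <- assembleModel("EMIL_M", 86)
  for (ps in c(86L, 129L)) {
    x <- array(runif(ps * ps * 3 * 2), c(ps, ps, 3L, 2L))
    E <- SparseMIL:::.subnet1Forward(x, m@weights$s1)$E
    expect_identical(dim(E), c(2L, 128L))
    expect_true(all(is.finite(E)))
  }
})

test_that("show methods print a readable summary", {
  expect_output(show(buildSubnet1()), "245,792")
  set.seed(1)
  expect_output(show(assembleModel("IMIL_SA", 86, lambdaL0 = 0.005)),
                "sparsemax")
  expect_output(show(sparsemaxTransform(c(2, 0))), "support 1")
})
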