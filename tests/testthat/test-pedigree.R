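test_that("pedigree parsing validates, sorts topologically and is idempotent", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,dam,sire,sex", "o,d,s,female", "d,NA,NA,female",
               "s,NA,NA,male"), path)
  ped <- read_pedigree(path)
  expect_s3_class(ped, "pedigree")
  expect_equal(nrow(ped), 3)
  expect_equal(ped$id[3], "o") # child last after topological sort

  # order-invariance: same pedigree no matter the row order in the file
  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,dam,sire,sex", "d,NA,NA,female", "s,NA,NA,male",
               "o,d,s,female"), path2)
  expect_identical(as.data.frame(read_pedigree(path2)), as.data.frame(ped))

  # tab dialect with empty-string unknowns
  path3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tdam\tsire\tsex", "o\td\ts\tf", "d\t\t\tf", "s\t\t\tm"), path3)
  expect_identical(as.data.frame(read_pedigree(path3)), as.data.frame(ped))

  # round-trip through the writer
  out <- withr::local_tempfile(fileext = ".tsv")
  write_pedigree(ped, out)
  expect_identical(as.data.frame(read_pedigree(out)), as.data.frame(ped))
})

test_that("invalid pedigrees are rejected with informative errors", {
  expect_error(pedigree(c("a", "a"), c(NA, NA), c(NA, NA), c("f", "m")),
               "duplicate id")
  # same id as both dam and sire
  expect_error(pedigree(c("p", "x", "y"), c(NA, "p", NA), c(NA, NA, "p"),
                        c("f", "f", "m")),
               "both dam and sire")
  # named dam is male
  expect_error(pedigree(c("p", "x"), c("p", NA), c(NA, NA), c("m", "f")),
               "dam is not female")
  expect_error(pedigree(c("p", "x"), c(NA, NA), c("p", NA), c("f", "m")),
               "sire is not male")
  # cycle: an individual its own ancestor
  expect_error(pedigree(c("a", "b", "c"), c("c", "a", "b"), c(NA, NA, NA),
                        c("f", "f", "f")),
               "cycle")
  expect_error(pedigree("a", NA, NA, "unknown"), "unknown sex code")
  expect_error(pedigree("a", NA, NA, NA), "sex")
})

test_that("additive relationship matrix reproduces textbook values", {
  # founders only -> identity
  ped <- founder_pedigree(4)
  expect_equal(additive_relationship(ped)$A, diag(4), ignore_attr = TRUE)

  # trio with unrelated parents
  ped <- pedigree(c("d", "s", "o"), c(NA, NA, "d"), c(NA, NA, "s"),
                  c("f", "m", "f"))
  rel <- additive_relationship(ped)
  expect_equal(rel$A["o", "d"], 0.5)
  expect_equal(rel$A["o", "s"], 0.5)
  expect_equal(rel$A["o", "o"], 1.0)
  expect_equal(rel$A["d", "s"], 0)
  expect_equal(unname(rel$F), rep(0, 3))

  # full sibs of unrelated non-inbred parents have A = 0.5 exactly
  ped <- pedigree(c("d", "s", "b1", "b2"), c(NA, NA, "d", "d"),
                  c(NA, NA, "s", "s"), c("f", "m", "m", "f"))
  expect_equal(additive_relationship(ped)$A["b1", "b2"], 0.5)

  # mating two full sibs: their offspring has F = 0.25, diagonal 1.25
  ped <- pedigree(c("d", "s", "b", "c", "o"), c(NA, NA, "d", "d", "c"),
                  c(NA, NA, "s", "s", "b"), c("f", "m", "m", "f", "f"))
  rel <- additive_relationship(ped)
  expect_equal(unname(rel$F["o"]), 0.25)
  expect_equal(rel$A["o", "o"], 1.25)
})

test_that("relationship values are invariant to input row order and PSD", {
  ped1 <- random_pedigree(10, 40, seed = 2)
  perm <- sample(nrow(ped1))
  df <- as.data.frame(ped1)[perm, ]
  ped2 <- pedigree(df$id, df$dam, df$sire, df$sex)
  A1 <- additive_relationship(ped1)$A
  A2 <- additive_relationship(ped2)$A
  expect_equal(A1[ped1$id, ped1$id], A2[ped1$id, ped1$id])

  for (seed in 1:5) {
    A <- additive_relationship(random_pedigree(12, 60, seed = seed))$A
    expect_gte(min(eigen(A, symmetric = TRUE, only.values = TRUE)$values),
               -1e-8)
  }
})

test_that("inverse relationship matrix matches the dense inverse", {
  # founders only -> identity
  expect_equal(as.matrix(inverse_relationship(founder_pedigree(5))), diag(5),
               ignore_attr = TRUE)

  # trio: defining property A^-1 A = I
  ped <- pedigree(c("d", "s", "o"), c(NA, NA, "d"), c(NA, NA, "s"),
                  c("f", "m", "f"))
  prod <- as.matrix(inverse_relationship(ped) %*% additive_relationship(ped)$A)
  expect_lt(max(abs(prod - diag(3))), 1e-10)

  # 300-individual random pedigree vs dense numerical inversion
  ped <- random_pedigree(40, 260, seed = 7)
  A <- additive_relationship(ped)$A
  Ainv <- as.matrix(inverse_relationship(ped))
  expect_lt(max(abs(Ainv - solve(A))), 1e-6)
  expect_lt(max(abs(A %*% Ainv - diag(nrow(A)))), 1e-8)
})

test_that("inbreeding propagates through the inverse assembly", {
  # repeated full-sib mating: strong inbreeding, one-parent-known branch
  ped <- pedigree(c("d", "s", "b", "c", "o", "q"),
                  c(NA, NA, "d", "d", "c", "c"),
                  c(NA, NA, "s", "s", "b", NA),
                  c("f", "m", "m", "f", "f", "m"))
  A <- additive_relationship(ped)$A
  Ainv <- as.matrix(inverse_relationship(ped))
  expect_lt(max(abs(Ainv %*% A - diag(nrow(A)))), 1e-10)
})
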