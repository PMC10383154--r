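test_that("worked excess-ADR examples reproduce from printed frequencies", {
  # warfarin / VKORC1: dominant, 0.674 vs 0.338
  expect_equal(excessADR(0.674, 0.338, "dominant"), 331.968,
               tolerance = 1e-12)
  expect_equal(roundADR(excessADR(0.674, 0.338, "dominant")), 332)
  # CYP3A4: dominant, 0.725 vs 0.105
  expect_equal(excessADR(0.725, 0.105, "dominant"), 725.4, tolerance = 1e-12)
  # MTHFR / methotrexate: dominant, excess in the higher-frequency group
  expect_equal(excessADR(0.348, 0.104, "dominant"), 377.712,
               tolerance = 1e-12)
  # IKBKB / gefitinib: recessive, 0.920 vs 0.333
  expect_equal(excessADR(0.920, 0.333, "recessive"), 735.511,
               tolerance = 1e-12)
  # extremes and equality
  expect_equal(excessADR(1, 0, "dominant"), 1000)
  expect_equal(excessADR(0.3, 0.3, "dominant"), 0)
  expect_equal(excessADR(0.3, 0.3, "recessive"), 0)
  expect_error(excessADR(1.1, 0.5, "dominant"), "\\[0, 1\\]")
  expect_error(excessADR(0.5, 0.5, "additive"))
})

test_that("algebraic identities hold on a dense frequency grid", {
  g <- seq(0, 1, length.out = 101)
  grid <- expand.grid(a = g, b = g)
  for (mode in c("dominant", "recessive")) {
    x <- excessADR(grid$a, grid$b, mode)
    expect_true(all(x >= -1000 & x <= 1000))
    # antisymmetry
    expect_lt(max(abs(x + excessADR(grid$b, grid$a, mode))), 1e-9)
  }
  # dominant == carrier-fraction difference x 1000
  carrier <- 1000 * ((1 - (1 - grid$a)^2) - (1 - (1 - grid$b)^2))
  expect_lt(max(abs(excessADR(grid$a, grid$b, "dominant") - carrier)), 1e-9)

  # strict monotonicity: increasing in p_a, decreasing in p_b on (0,1)
  p <- seq(0.01, 0.99, by = 0.01)
  for (mode in c("dominant", "recessive")) {
    expect_true(all(diff(excessADR(p, 0.5, mode)) > 0))
    expect_true(all(diff(excessADR(0.5, p, mode)) < 0))
  }
})

test_that("closed form matches a brute-force population enumeration", {
  # deterministic enumeration: N individuals with exact HWE genotype counts
  enum <- function(p_a, p_b, mode, N = 1e7) {
    affected <- function(p) {
      counts <- round(N * c(p^2, 2 * p * (1 - p), (1 - p)^2))
      if (mode == "recessive") counts[1] else counts[1] + counts[2]
    }
    1000 * (affected(p_a) - affected(p_b)) / N
  }
  set.seed(71)
  for (i in 1:20) {
    pa <- runif(1)
    pb <- runif(1)
    mode <- sample(c("dominant", "recessive"), 1)
    expect_lt(abs(enum(pa, pb, mode) - excessADR(pa, pb, mode)), 1000 / 1e7 * 2)
  }
})

test_that("the ADR table orients effect alleles and signs per group", {
  ex <- examplePGxData()
  tab <- suppressMessages(adrTable(ex$frequencies, ex$annotation, "White"))
  expect_equal(nrow(tab), 4L)
  get <- function(rs) tab[tab$rsid == rs, ]

  warf <- get("rs9923231")
  expect_equal(warf$excess_reported, 332)
  expect_identical(warf$direction, "Asian")

  tac <- get("rs4646437")
  expect_equal(tac$excess_per_1000, 725.4, tolerance = 1e-9)
  expect_identical(tac$direction, "Black")

  mtx <- get("rs1801133")
  expect_equal(mtx$excess_per_1000, -377.712, tolerance = 1e-9)
  expect_identical(mtx$direction, "White")

  gef <- get("rs9694958")
  expect_equal(gef$excess_per_1000, -735.511, tolerance = 1e-9)
  expect_identical(gef$direction, "White")
  expect_identical(gef$mode, "recessive")
})

test_that("ADR table handles orientation flips, self-reference and unknowns", {
  ann <- new("PGxAnnotation", S4Vectors::DataFrame(data.frame(
    variant_id = "chr1:10:C:T", rsid = "rs1", gene = "G", drugs = "d",
    evidence_level = "3", association_type = "toxicity",
    mode_of_effect = "recessive", effect_allele = "C")))  # effect = ref
  fr <- new("GroupFrequencyTable", S4Vectors::DataFrame(data.frame(
    variant_id = "chr1:10:C:T", rsid = "rs1", group = c("X", "Y"),
    allele = "T", freq = c(0.4, 0.1), n_called = 10L)))
  tab <- adrTable(fr, ann, "Y")
  # alt freq 0.4/0.1 -> effect (ref) freq 0.6/0.9
  expect_equal(tab$p_group, 0.6)
  expect_equal(tab$p_reference, 0.9)
  expect_equal(tab$excess_per_1000, 1000 * (0.36 - 0.81))

  # reference vs itself: nothing to compare -> zero rows for that group
  tab2 <- adrTable(fr, ann, "X")
  expect_true(all(tab2$group != "X"))

  # unknown-mode-only annotation: empty output with a message
  ann_unknown <- new("PGxAnnotation", S4Vectors::DataFrame(data.frame(
    variant_id = "chr1:10:C:T", rsid = "rs1", gene = "G", drugs = "d",
    evidence_level = "3", association_type = "toxicity",
    mode_of_effect = "unknown", effect_allele = "C")))
  expect_message(empty <- adrTable(fr, ann_unknown, "Y"), "unknown mode")
  expect_equal(nrow(empty), 0L)

  expect_error(adrTable(fr, ann, "Nope"), "absent")
})
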