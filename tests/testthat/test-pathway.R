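toy_db <- function() {
  data.frame(
    compound_id = c("c1", "c2", "c3", "c4", "c5", "c6", "c7", "c8", "c9"),
    formula     = c("C6H12O6", "C6H12O6", "C6H12O6",  # 3 isomers
                    "C5H10O5", "C5H10O5",
                    "C10H12O5", "C7H6O2", "C7H6O2", "C9H8O4"),
    pathway_id  = c("pwA", "pwA", "pwA",
                    "pwA", "pwB",
                    "pwB", "pwA", "pwB", "pwC"),
    pathway_size = c(10, 10, 10, 10, 5, 5, 10, 5, 4),
    stringsAsFactors = FALSE)
}

test_that("match rate and multiplicity mirror their definitions", {
  db <- toy_db()
  # 1 of 5 assigned formulas matches -> 20 %
  m <- match_formulas(c("C6H12O6", "X1", "X2", "X3", "X4")[c(1:5)], db)
  expect_equal(m$match_rate, 0.2)
  # multiplicities 1, 2, 6 -> mean 3.0
  db2 <- data.frame(
    compound_id = c("a1", "b1", "b2", paste0("c", 1:6)),
    formula = c("F1", "F2", "F2", rep("F3", 6)),
    pathway_id = "pw",
    stringsAsFactors = FALSE)
  db2$formula <- sub("F1", "C6H12O6", db2$formula)
  db2$formula <- sub("F2", "C5H10O5", db2$formula)
  db2$formula <- sub("F3", "C7H6O2", db2$formula)
  m2 <- match_formulas(c("C6H12O6", "C5H10O5", "C7H6O2"), db2)
  expect_equal(m2$mean_multiplicity, 3.0)
  expect_equal(m2$match_rate, 1.0)
  # formula absent from the DB: zero matches
  m3 <- match_formulas("C99H99O99", db)
  expect_equal(nrow(m3$per_formula), 0L)
  expect_equal(m3$match_rate, 0)
  # empty DB: all unmatched
  m4 <- match_formulas("C6H12O6", db[0, ])
  expect_equal(m4$match_rate, 0)
})

test_that("pathway intensity allows one contribution per formula per pathway", {
  db <- toy_db()
  m <- match_formulas("C6H12O6", db)
  # 3 isomers in pwA: the 0.1 intensity counts once, not three times
  pi1 <- pathway_intensity(m, c(C6H12O6 = 0.1))
  expect_equal(pi1$intensity[pi1$pathway_id == "pwA"], 0.1)
  # a formula matching 2 pathways contributes once to each
  m2 <- match_formulas("C5H10O5", db)
  pi2 <- pathway_intensity(m2, c(C5H10O5 = 0.1))
  expect_equal(pi2$intensity[pi2$pathway_id == "pwA"], 0.1)
  expect_equal(pi2$intensity[pi2$pathway_id == "pwB"], 0.1)
  # no matches: all pathway intensities 0
  m0 <- match_formulas("C99H99O99", db)
  pi0 <- pathway_intensity(m0, c(C99H99O99 = 0.5))
  expect_true(all(pi0$intensity == 0))
  expect_setequal(pi0$pathway_id, c("pwA", "pwB", "pwC"))
  # missing intensity for a matched formula names the formula
  expect_error(pathway_intensity(m, c(C5H10O5 = 0.1)), "C6H12O6")
})

test_that("duplicating a DB record never changes pathway intensities", {
  db <- toy_db()
  formulas <- c("C6H12O6", "C5H10O5", "C7H6O2")
  intens <- c(C6H12O6 = 0.2, C5H10O5 = 0.3, C7H6O2 = 0.05)
  base <- pathway_intensity(match_formulas(formulas, db), intens)
  for (i in seq_len(nrow(db))) {
    dup <- rbind(db, db[i, ])
    got <- pathway_intensity(match_formulas(formulas, dup), intens)
    expect_equal(got, base)
  }
})

test_that("coverage matches its definition and a set-intersection oracle", {
  db <- toy_db()
  # pwA size 10, detected compounds c1,c2,c3,c4 from two formulas -> 0.4
  cov <- pathway_coverage(match_formulas(c("C6H12O6", "C5H10O5"), db), db)
  expect_equal(cov$coverage[cov$pathway_id == "pwA"], 0.4)
  # all members detected -> 1.0
  dbx <- data.frame(compound_id = c("z1", "z2"), formula = c("F", "G"),
                    pathway_id = "pwZ", pathway_size = 2)
  dbx$formula <- c("C6H12O6", "C5H10O5")
  covx <- pathway_coverage(match_formulas(c("C6H12O6", "C5H10O5"), dbx), dbx)
  expect_equal(covx$coverage, 1.0)
  # random toy DBs against brute-force set intersection
  set.seed(41)
  pg <- expand.grid(C = 5:20, O = 1:8)
  pool <- mapply(function(C, O) formula_string(c(C = C, H = 2 * C, O = O)),
                 pg$C, pg$O)
  for (rep in 1:5) {
    dbr <- data.frame(
      compound_id = paste0("k", 1:60),
      formula = sample(pool, 60, replace = TRUE),
      pathway_id = sample(paste0("pw", 1:6), 60, replace = TRUE),
      stringsAsFactors = FALSE)
    sizes <- tapply(dbr$compound_id, dbr$pathway_id,
                    function(v) length(unique(v))) + 5L
    dbr$pathway_size <- as.integer(sizes[dbr$pathway_id])
    detected <- sample(pool, 30)
    got <- pathway_coverage(match_formulas(detected, dbr), dbr)
    for (pw in unique(dbr$pathway_id)) {
      rows <- dbr[dbr$pathway_id == pw, ]
      orc <- length(unique(rows$compound_id[rows$formula %in% detected])) /
        rows$pathway_size[1]
      expect_equal(got$coverage[got$pathway_id == pw], min(orc, 1))
    }
  }
  # adding formulas never decreases coverage
  c1 <- pathway_coverage(match_formulas("C6H12O6", db), db)
  c2 <- pathway_coverage(match_formulas(c("C6H12O6", "C7H6O2"), db), db)
  expect_true(all(c2$coverage >= c1$coverage))
  # size-zero pathways excluded with a warning
  db0 <- rbind(db, data.frame(compound_id = "zz", formula = "C2H6O",
                              pathway_id = "pw0", pathway_size = 0))
  expect_warning(cz <- pathway_coverage(match_formulas("C2H6O", db0), db0),
                 "size zero")
  expect_false("pw0" %in% cz$pathway_id)
})

test_that("coverage dispersion matches hand arithmetic", {
  M <- rbind(pwA = c(0.4, 0.6), pwB = c(0.3, 0.3))
  d <- coverage_dispersion(M)
  expect_equal(d$per_pathway$sd[d$per_pathway$pathway_id == "pwA"],
               sd(c(0.4, 0.6)))
  expect_equal(d$per_pathway$sd[d$per_pathway$pathway_id == "pwB"], 0)
  expect_equal(d$mean_sd, mean(c(sd(c(0.4, 0.6)), 0)))
  # identical groups: all-zero dispersion
  d0 <- coverage_dispersion(cbind(c(0.2, 0.5), c(0.2, 0.5)))
  expect_equal(d0$mean_sd, 0)
  expect_error(coverage_dispersion(matrix(0.5, 3, 1)), "2 groups")
  # list-of-coverage-tables input joins on pathway id
  db <- toy_db()
  g1 <- pathway_coverage(match_formulas("C6H12O6", db), db)
  g2 <- pathway_coverage(match_formulas(c("C6H12O6", "C5H10O5"), db), db)
  dl <- coverage_dispersion(list(a = g1, b = g2))
  expect_equal(nrow(dl$per_pathway), 3L)
})

test_that("cross-dataset coverage comparison classifies quadrants", {
  dom <- data.frame(pathway_id = c("p1", "p2", "p3", "p4"),
                    coverage = c(0.8, 0.8, 0.1, 0.1))
  oth <- data.frame(pathway_id = c("p1", "p2", "p3", "p5"),
                    coverage = c(0.9, 0.2, 0.7, 0.4))
  cmp <- compare_coverage(dom, oth, threshold = 0.5)
  q <- setNames(cmp$quadrant, cmp$pathway_id)
  expect_equal(unname(q["p1"]), "both-high")
  expect_equal(unname(q["p2"]), "dom-only")
  expect_equal(unname(q["p3"]), "other-only")
  # one-sided pathways kept with a missing flag, not dropped
  expect_true("p4" %in% cmp$pathway_id && "p5" %in% cmp$pathway_id)
  expect_equal(cmp$missing_in[cmp$pathway_id == "p4"], "other")
  expect_equal(cmp$missing_in[cmp$pathway_id == "p5"], "dom")
  # threshold 0: every shared pathway is both-high
  cmp0 <- compare_coverage(dom, oth, threshold = 0)
  expect_true(all(cmp0$quadrant[cmp0$missing_in == ""] == "both-high"))
  # disjoint tables warn
  expect_warning(compare_coverage(
    data.frame(pathway_id = "a", coverage = 1),
    data.frame(pathway_id = "b", coverage = 1)), "share no pathways")
})
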