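test_that("Pielou evenness matches the Shannon formula and its bounds", {
  expect_equal(pielou_evenness(c(10, 10, 10, 10)), 1)
  expect_true(is.na(pielou_evenness(42)))
  # hand evaluation of -(0.75 ln 0.75 + 0.25 ln 0.25)/ln 2
  expect_equal(pielou_evenness(c(3, 1)),
               -(0.75 * log(0.75) + 0.25 * log(0.25)) / log(2),
               tolerance = 1e-12)
  # direct Shannon-formula oracle on random 2-5 species vectors
  set.seed(1)
  for (s in 2:5) {
    v <- rexp(s) + 0.1
    p <- v / sum(v)
    expect_equal(pielou_evenness(v), -sum(p * log(p)) / log(s),
                 tolerance = 1e-12)
  }
  expect_error(pielou_evenness(c(1, 0)), class = "sporoscale_domain_error")
})

test_that("evenness is scale-invariant and maximal at equal shares", {
  set.seed(7)
  for (i in 1:20) {
    v <- rexp(sample(2:8, 1)) + 0.05
    expect_equal(pielou_evenness(v), pielou_evenness(v * runif(1, 0.1, 100)),
                 tolerance = 1e-12)
    # mean-preserving transfer between two species lowers J
    j <- sample(length(v), 2)
    w <- v
    d <- 0.5 * min(w[j])
    hi <- j[which.max(w[j])]; lo <- j[which.min(w[j])]
    if (hi != lo) {
      w[hi] <- w[hi] + d
      w[lo] <- w[lo] - d
      expect_lt(pielou_evenness(w), pielou_evenness(v) + 1e-12)
    }
  }
})

test_that("evenness agrees with vegan's Shannon-based computation", {
  skip_if_not_installed("vegan")
  set.seed(2)
  v <- rexp(6)
  expect_equal(pielou_evenness(v),
               as.numeric(vegan::diversity(v) / log(6)), tolerance = 1e-12)
})

test_that("response transformations behave on boundaries and bad input", {
  expect_equal(transform_response(c(0, 4, 9), "sqrt"), c(0, 2, 3))
  expect_equal(transform_response(c(0, 1), "arcsine_sqrt"), c(0, pi / 2))
  expect_equal(transform_response(0, "log1p"), 0)
  err <- tryCatch(transform_response(c(1, -2), "sqrt"), error = identity)
  expect_s3_class(err, "sporoscale_domain_error")
  expect_match(conditionMessage(err), "index 2")
  expect_error(transform_response(c(0.5, 1.2), "arcsine_sqrt"),
               class = "sporoscale_domain_error")
})

test_that("plot-year aggregation scales biomass by area and counts taxa", {
  py <- aggregate_plot_year(tiny_records(), tiny_meta())
  # 1.5 kg on 100 m2 -> 150 kg/ha
  expect_equal(py$biomass_kg_ha, 150)
  expect_equal(py$richness_S, 2L)  # taxa {A, A, B}
  # evenness from annual species biomass (A: 1200 g, B: 300 g)
  expect_equal(py$evenness_J, pielou_evenness(c(1200, 300)))

  # guild scoping
  pm <- aggregate_plot_year(tiny_records(), tiny_meta(),
                            scope = "mycorrhizal")
  ps <- aggregate_plot_year(tiny_records(), tiny_meta(),
                            scope = "saprotrophic")
  expect_equal(pm$biomass_kg_ha, 120)
  expect_equal(ps$biomass_kg_ha, 30)
  expect_equal(pm$richness_S + ps$richness_S, py$richness_S)

  # unknown plot is a referential error
  bad <- tiny_records(); bad$plot_id <- "zz"
  expect_error(aggregate_plot_year(bad, tiny_meta()),
               class = "sporoscale_referential_error")
})

test_that("biomass partitions exactly across guilds on a full survey", {
  sv <- default_survey()
  tot <- aggregate_plot_year(sv$records, sv$meta)
  myc <- aggregate_plot_year(sv$records, sv$meta, scope = "mycorrhizal")
  sap <- aggregate_plot_year(sv$records, sv$meta, scope = "saprotrophic")
  key <- function(d) paste(d$plot_id, d$year)
  im <- match(key(tot), key(myc)); is <- match(key(tot), key(sap))
  expect_equal(tot$biomass_kg_ha,
               myc$biomass_kg_ha[im] + sap$biomass_kg_ha[is],
               tolerance = 1e-9)
  expect_true(all(tot$richness_S >=
                  pmax(myc$richness_S[im], sap$richness_S[is])))
  # sampled-but-empty plot-years would appear as zeros, never dropped
  expect_equal(nrow(tot), nrow(sv$meta) * length(unique(sv$plot_year$year)))

  # biomass aggregation is additive over arbitrary record partitions
  set.seed(3)
  split_idx <- sample(c(TRUE, FALSE), nrow(sv$records), replace = TRUE)
  a <- aggregate_plot_year(sv$records[split_idx, ], sv$meta,
                           plot_years = tot[, c("plot_id", "year")])
  b <- aggregate_plot_year(sv$records[!split_idx, ], sv$meta,
                           plot_years = tot[, c("plot_id", "year")])
  expect_equal(a$biomass_kg_ha + b$biomass_kg_ha, tot$biomass_kg_ha,
               tolerance = 1e-9)
})
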