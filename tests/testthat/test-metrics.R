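test_that("NAD matches its definition on worked examples", {
  scheme <- toy_parcellation(20, 1)  # two networks of 10 parcels
  imp <- rep(FALSE, 20); imp[c(1, 4, 7)] <- TRUE  # 3 of 10 in network 1
  tab <- nad(imp, scheme)
  expect_equal(tab$nad[tab$hemisphere == "left"], 30.0)
  expect_equal(tab$nad[tab$hemisphere == "right"], 0)
  expect_true(all(nad(rep(FALSE, 20), scheme)$nad == 0))
  expect_true(all(nad(rep(TRUE, 20), scheme)$nad == 100))
  expect_equal(sum(tab$K), 20L)
})

test_that("GD counts altered networks", {
  tab <- tibble::tibble(n_impaired = c(0L, 0L, 3L, 10L),
                        nad = c(0, 0, 30, 100))
  expect_equal(gd(tab), 2L)
  expect_equal(gd(tibble::tibble(n_impaired = rep(0L, 36))), 0L)
  expect_equal(gd(tibble::tibble(n_impaired = rep(1L, 36))), 36L)
})

test_that("overlap index follows its ratio definition", {
  expect_equal(overlap_index(c("a", "b", "c", "d"), c("a", "b", "x")), 50.0)
  expect_equal(overlap_index(c("a", "b"), c("x", "y")), 0)
  expect_true(is.na(overlap_index(character(0), c("a"))))
  # subset property: OI = 100 when single set is contained in integrated
  expect_equal(overlap_index(c("a", "b"), c("a", "b", "c")), 100)
  # invariance to relabeling
  expect_equal(overlap_index(c("b", "a"), c("a", "b", "c")), 100)
})

test_that("NAD/GD/OI match brute-force oracles over all 6-parcel patterns", {
  scheme <- six_parcel_scheme()
  nets <- networks(scheme)
  patterns <- expand.grid(rep(list(c(FALSE, TRUE)), 6))
  # NAD and GD oracles by direct enumeration
  for (i in seq_len(nrow(patterns))) {
    imp <- unlist(patterns[i, ])
    tab <- nad(imp, scheme)
    for (k in nets$network_key) {
      members <- scheme$network_key == k
      expect_equal(tab$nad[tab$network_key == k],
                   100 * sum(imp[members]) / sum(members))
    }
    gd_oracle <- sum(vapply(nets$network_key, function(k)
      any(imp[scheme$network_key == k]), logical(1)))
    expect_equal(gd(tab), gd_oracle)
  }
  # OI oracle over pairs of patterns (single-modality vs integrated)
  altered_nets <- function(imp) {
    unique(scheme$network_key[imp])
  }
  set.seed(24)
  pick <- sample.int(nrow(patterns), 16)
  for (i in pick) for (j in pick) {
    single <- altered_nets(unlist(patterns[i, ]))
    integ <- altered_nets(unlist(patterns[j, ]))
    oracle <- if (length(single) == 0) NA_real_
              else 100 * sum(single %in% integ) / length(single)
    expect_equal(overlap_index(single, integ), oracle)
  }
})

test_that("two-path GD equivalence holds over random patterns", {
  scheme <- toy_parcellation(24, 3)
  set.seed(25)
  for (rep in 1:20) {
    imp <- runif(24) < 0.3
    tab <- nad(imp, scheme)
    direct <- length(unique(scheme$network_key[imp]))
    expect_equal(gd(tab), direct)
  }
})

test_that("tissue stratification applies tumor > edema > healthy precedence", {
  scheme <- six_parcel_scheme()
  rec <- subject_records(tibble::tibble(
    subject_id = "g", cohort = "glioma", split = "test",
    lesion_hemisphere = "left", volume_T = 1, volume_TO = 2,
    tumor_fraction = list(c(0.2, 0, 0, 0, 0, 0)),
    edema_fraction = list(c(0, 0.5, 0, 0.3, 0, 0))), scheme = scheme)
  tc <- stratify_by_tissue(rec, scheme)
  expect_equal(tc$tissue_class[tc$network_key == "left:A"], "tumor")
  expect_equal(tc$tissue_class[tc$network_key == "right:B"], "edema")
  expect_equal(tc$tissue_class[tc$network_key == "right:C"], "healthy")
  # all-zero fractions -> healthy everywhere
  rec0 <- subject_records(tibble::tibble(
    subject_id = "h", cohort = "healthy", split = "test"),
    scheme = scheme)
  expect_true(all(stratify_by_tissue(rec0, scheme)$tissue_class == "healthy"))
})

make_metrics <- function(id, fc, sc, fcsc, scheme, rec) {
  anomaly <- structure(list(
    subject_id = id,
    impaired = list(FC = fc, SC = sc, FCSC = fcsc)), class = "connvae_anomaly")
  network_metrics(anomaly, rec, scheme)
}

test_that("cohort summaries partition altered networks exclusively", {
  scheme <- six_parcel_scheme()
  rec <- subject_records(tibble::tibble(
    subject_id = "g1", cohort = "glioma", split = "test",
    lesion_hemisphere = "left", volume_T = 1, volume_TO = 2,
    tumor_fraction = list(c(1, 0, 0, 0, 0, 0)),
    edema_fraction = list(rep(0, 6))), scheme = scheme)
  # one FC-only altered network (right:C via parcel 6)
  fc <- c(rep(FALSE, 5), TRUE)
  m1 <- make_metrics("g1", fc, rep(FALSE, 6), rep(FALSE, 6), scheme, rec)
  s1 <- cohort_summary(list(m1))
  expect_equal(nrow(s1), 1L)
  expect_equal(s1$combination, "FC_only")
  expect_equal(s1$pct_subjects, 100)
  expect_equal(s1$tissue_class, "healthy")

  # partition conservation across several subjects
  rec2 <- rec; rec2$subject_id <- "g2"
  m2 <- make_metrics("g2", fc, fc, fc, scheme, rec2)  # FC&SC&FCSC at right:C
  rec3 <- rec; rec3$subject_id <- "g3"
  m3 <- make_metrics("g3", rep(FALSE, 6), fc, fc, scheme, rec3)  # SC&FCSC
  s <- cohort_summary(list(m1, m2, m3))
  cell <- s[s$network_key == "right:C", ]
  # every altered occurrence of right:C lands in exactly one combination
  expect_equal(sum(cell$n_altered), 3L)
  expect_setequal(cell$combination,
                  c("FC_only", "FC_and_SC_and_FCSC", "SC_and_FCSC"))
})

test_that("tissue_frequency conditions on class membership", {
  scheme <- six_parcel_scheme()
  rec_for <- function(id, tumor_parcel) {
    tf <- rep(0, 6); tf[tumor_parcel] <- 1
    subject_records(tibble::tibble(
      subject_id = id, cohort = "glioma", split = "test",
      lesion_hemisphere = "left", volume_T = 1, volume_TO = 1,
      tumor_fraction = list(tf), edema_fraction = list(rep(0, 6))),
      scheme = scheme)
  }
  # subject 1: tumor in left:A (parcel 1), SC-altered there
  m1 <- make_metrics("s1", rep(FALSE, 6), c(TRUE, rep(FALSE, 5)),
                     rep(FALSE, 6), scheme, rec_for("s1", 1))
  # subject 2: tumor in right:C (parcel 6), nothing altered
  m2 <- make_metrics("s2", rep(FALSE, 6), rep(FALSE, 6), rep(FALSE, 6),
                     scheme, rec_for("s2", 6))
  freq <- tissue_frequency(list(m1, m2))
  # tumor-class occurrences: left:A (s1) and right:C (s2); SC altered in 1/2
  expect_equal(freq$pct_altered[freq$tissue_class == "tumor" &
                                  freq$modality == "SC"], 50)
  expect_equal(freq$n_occurrences[freq$tissue_class == "tumor" &
                                    freq$modality == "SC"], 2L)
  # healthy-class occurrences: 2 per subject (3 networks - 1 tumor) = 4
  expect_equal(freq$n_occurrences[freq$tissue_class == "healthy" &
                                    freq$modality == "FC"], 4L)
  expect_true(all(freq$pct_altered[freq$tissue_class == "healthy"] == 0))
})

test_that("volume associations use the right statistic and BH correction", {
  set.seed(26)
  df <- tibble::tibble(
    gd = 1:10,
    vol_linear = 3 * (1:10) + 2,
    vol_monotone = exp(1:10 / 2),
    noise = rnorm(10))
  a1 <- associate_with_volume(df, "gd", "vol_linear", "pearson")
  expect_equal(a1$estimate, 1.0)
  a2 <- associate_with_volume(df, "gd", "vol_monotone", "spearman")
  expect_equal(a2$estimate, 1.0)
  a3 <- associate_with_volume(df, "gd", "vol_monotone", "pearson")
  expect_lt(a3$estimate, 1)
  # degenerate input -> sentinel
  df$flat <- 1
  a4 <- associate_with_volume(df, "flat", "vol_linear", "pearson")
  expect_true(is.na(a4$estimate))
  expect_error(associate_with_volume(df[1:2, ], "gd", "vol_linear", "pearson"),
               class = "connvae_format_error")

  # BH step-up oracle on the family of adjusted p-values
  df2 <- tibble::tibble(a = rnorm(20), b = rnorm(20), c = rnorm(20),
                        v1 = rnorm(20), v2 = rnorm(20))
  res <- associate_with_volume(df2, c("a", "b", "c"), c("v1", "v2"),
                               "pearson")
  p <- res$p_value
  mtests <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  oracle <- pmin(1, cummin(mtests / (mtests:1) * p[o]))[ro]
  expect_equal(res$p_adjusted, oracle, tolerance = 1e-12)
})

test_that("metric tidiers expose NAD tables and GD/OI summaries", {
  scheme <- six_parcel_scheme()
  rec <- subject_records(tibble::tibble(
    subject_id = "g1", cohort = "glioma", split = "test",
    lesion_hemisphere = "left", volume_T = 10, volume_TO = 20,
    tumor_fraction = list(c(1, 0, 0, 0, 0, 0)),
    edema_fraction = list(rep(0, 6))), scheme = scheme)
  m <- make_metrics("g1", c(TRUE, TRUE, FALSE, FALSE, FALSE, TRUE),
                    c(TRUE, rep(FALSE, 5)), c(TRUE, rep(FALSE, 5)),
                    scheme, rec)
  gl <- glance(m)
  expect_equal(gl$gd_fc, 2)
  expect_equal(gl$gd_sc, 1)
  expect_equal(gl$oi_fc, 50)   # {left:A, right:C} vs {left:A}
  expect_equal(gl$oi_sc, 100)
  td <- tidy(m)
  expect_equal(nrow(td), 9L)  # 3 networks x 3 modalities
  expect_true(all(c("nad", "tissue_class") %in% names(td)))
})
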