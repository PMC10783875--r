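clean_record <- function(assay = "A1", ligand = "L1", value = 100,
                         type = "IC50") {
  data.frame(assay_id = assay, target_id = "T1", ligand_id = ligand,
             standard_type = type, standard_relation = "=",
             standard_value = value, standard_units = "nM",
             assay_type = "B", target_type = "SINGLE PROTEIN",
             component_type = "PROTEIN", molecule_type = "Small molecule",
             bao_format = "BAO_0000357", stringsAsFactors = FALSE)
}

adversarial_table <- function() {
  recs <- clean_record(ligand = "Lc1")
  recs <- rbind(recs, clean_record(ligand = "Lc2", value = 5))
  bad <- list(
    standard_type = "EC50", standard_relation = ">", standard_units = "uM",
    assay_type = "F", target_type = "PROTEIN COMPLEX",
    component_type = "DNA", molecule_type = "Antibody",
    bao_format = "BAO_0000219"
  )
  for (nm in names(bad)) {
    r <- clean_record(ligand = paste0("Lbad_", nm))
    r[[nm]] <- bad[[nm]]
    recs <- rbind(recs, r)
  }
  recs
}

test_that("the eight curation filters remove offenders and keep clean records", {
  recs <- adversarial_table()
  out <- apply_chembl_filters(recs)
  expect_equal(nrow(out$records), 2L)
  expect_equal(out$records$ligand_id, c("Lc1", "Lc2"))
  # one removal per criterion, attributed in the listed order
  for (nm in c("standard_type", "standard_relation", "standard_units",
               "assay_type", "target_type", "component_type",
               "molecule_type", "bao_format")) {
    expect_equal(out$report$removed[[nm]], 1L)
  }
})

test_that("curation conserves records: survivors + removals = input", {
  recs <- adversarial_table()
  r <- clean_record(ligand = "Lmiss")
  r$standard_value <- NA
  recs <- rbind(recs, r)
  out <- apply_chembl_filters(recs)
  expect_equal(out$report$input,
               out$report$surviving + sum(unlist(out$report$removed)))
  expect_equal(out$report$removed$missing_field, 1L)
})

test_that("a record violating multiple criteria is counted once, at the first", {
  r <- clean_record()
  r$standard_relation <- ">"
  r$standard_units <- "uM"
  out <- apply_chembl_filters(r)
  expect_equal(out$report$removed$standard_relation, 1L)
  expect_equal(out$report$removed$standard_units, 0L)
})

test_that("assay grouping drops singletons and mixed-type assays", {
  recs <- rbind(
    clean_record("A1", "L1"),                      # size 1 -> dropped
    clean_record("A2", "L2", 10), clean_record("A2", "L3", 20),
    clean_record("A3", "L4", 10), clean_record("A3", "L5", 30),
    clean_record("A4", "L6", 1), clean_record("A4", "L7", 2),
    clean_record("A4", "L8", 3),
    clean_record("A5", "L9")                       # size 1 -> dropped
  )
  assays <- group_into_assays(recs)
  expect_equal(length(assays), 3L)
  expect_equal(sum(vapply(assays, `[[`, numeric(1), "size")), 7)
  mixed <- rbind(clean_record("A6", "La", 5, "Ki"),
                 clean_record("A6", "Lb", 9, "IC50"))
  expect_equal(length(group_into_assays(mixed)), 0L)
})

test_that("duplicate (assay, ligand) rows collapse to the geometric mean", {
  recs <- rbind(clean_record("A1", "L1", 10), clean_record("A1", "L1", 1000),
                clean_record("A1", "L2", 50))
  assays <- group_into_assays(recs)
  expect_equal(length(assays), 1L)
  v <- assays[[1]]$value_nM[assays[[1]]$ligand_id == "L1"]
  expect_equal(v, 100) # sqrt(10 * 1000)
})

test_that("Ki and Kd map to the merged K task, IC50 stays, others error", {
  expect_equal(map_label_type("Ki"), "K")
  expect_equal(map_label_type("Kd"), "K")
  expect_equal(map_label_type("IC50"), "IC50")
  expect_error(map_label_type("EC50"), "unsupported")
})

test_that("assay sampling is proportional to size", {
  assays <- group_into_assays(rbind(
    clean_record("A1", "L1", 1), clean_record("A1", "L2", 2),
    clean_record("A2", "L3", 1), clean_record("A2", "L4", 2),
    clean_record("A2", "L5", 3),
    clean_record("A3", "L6", 1), clean_record("A3", "L7", 2),
    clean_record("A3", "L8", 3), clean_record("A3", "L9", 4),
    clean_record("A3", "L10", 5)
  ))
  sizes <- vapply(assays, `[[`, numeric(1), "size")
  expect_equal(sort(sizes), c(2, 3, 5))
  set.seed(31)
  draws <- vapply(1:20000, function(i) sample_assay(assays)$assay_id, "")
  counts <- table(factor(draws, levels = vapply(assays, `[[`, "", "assay_id")))
  p <- sizes / sum(sizes)
  chi <- stats::chisq.test(as.vector(counts), p = p)
  expect_gt(chi$p.value, 0.001)
  # single assay is always selected
  expect_equal(sample_assay(assays[2])$assay_id, assays[[2]]$assay_id)
  expect_error(sample_assay(list()), "no assays")
})

test_that("pair sampling draws distinct ligands uniformly and handles ties", {
  a4 <- group_into_assays(rbind(
    clean_record("A1", "L1", 1), clean_record("A1", "L2", 2),
    clean_record("A1", "L3", 3), clean_record("A1", "L4", 4)))[[1]]
  set.seed(17)
  draws <- replicate(12000, {
    p <- sample_pair(a4)
    paste(sort(c(p$ligand_a, p$ligand_b)), collapse = "-")
  })
  counts <- table(draws)
  expect_equal(length(counts), 6L) # all unordered pairs occur
  chi <- stats::chisq.test(as.vector(counts), p = rep(1 / 6, 6))
  expect_gt(chi$p.value, 0.001)
  # a size-2 assay always yields the same unordered ligand set
  a2 <- group_into_assays(rbind(clean_record("A1", "A", 125),
                                clean_record("A1", "B", 0.65)))[[1]]
  p <- sample_pair(a2)
  expect_setequal(c(p$ligand_a, p$ligand_b), c("A", "B"))
  expect_equal(p$task_type, "IC50")
  # all-equal values exhaust the tie retries
  atie <- group_into_assays(rbind(clean_record("A1", "X", 7),
                                  clean_record("A1", "Y", 7)))[[1]]
  expect_error(sample_pair(atie), "untied")
})

test_that("ranking labels are the literal value comparison and antisymmetric", {
  expect_equal(ranking_label(125, 0.65), 1L)
  expect_equal(ranking_label(0.65, 125), 0L)
  expect_error(ranking_label(5, 5), "tied")
  set.seed(23)
  for (k in 1:200) {
    v <- stats::runif(2, 0.01, 1e5)
    if (v[1] == v[2]) next
    expect_equal(ranking_label(v[1], v[2]), as.integer(v[1] > v[2]))
    expect_equal(ranking_label(v[1], v[2]) + ranking_label(v[2], v[1]), 1L)
  }
})

test_that("pAff transform is 9 - log10(nM), strictly decreasing, and flips labels", {
  expect_equal(to_paffinity(1), 9)
  expect_equal(to_paffinity(1000), 6)
  expect_equal(to_paffinity(125), 9 - log10(125), tolerance = 1e-12)
  expect_error(to_paffinity(0), "positive")
  expect_error(to_paffinity(-5), "positive")
  v <- sort(stats::runif(20, 0.1, 1e6))
  expect_true(all(diff(to_paffinity(v)) < 0))
  expect_equal(from_paffinity(to_paffinity(v)), v, tolerance = 1e-9)
  # larger nM = weaker binding: the pAff comparison is the label's mirror
  expect_equal(ranking_label(125, 0.65),
               1L - as.integer(to_paffinity(125) > to_paffinity(0.65)))
})
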