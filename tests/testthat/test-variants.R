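test_that("linked regions are 1-Mbp half-open windows above the LOD cut", {
  res <- data.frame(gene = c("A", "B", "C"), chrom = "1",
                    pos = c(400000, 5e6, 9e6), scope = "7",
                    lod = c(1.2, 0.59, 0.61),
                    pvalue = c(0.01, 0.051, 0.049))
  reg <- linked_regions(res)
  expect_equal(reg$gene, c("A", "C"))
  # clipping at the chromosome start keeps the upper half-window
  expect_equal(reg$window_start[1], 1)
  expect_equal(reg$window_end[1], 900000)
  expect_equal(reg$window_end[2] - reg$window_start[2], 1e6)
  expect_equal(nrow(linked_regions(res[res$lod < 0.6, ])), 0L)
})

test_that("founder entry counts rare-allele founders and flags inconsistency", {
  trio <- ped_trio()
  g <- stats::setNames(c(1L, 0L, 1L), trio$id)
  expect_equal(founder_entry_count(trio, g), 1L)
  g2 <- stats::setNames(c(0L, 0L, 1L), trio$id)  # carrier child, no founder
  expect_warning(nf <- founder_entry_count(trio, g2), "inconsistent")
  expect_equal(nf, 0L)
  expect_error(founder_entry_count(trio, c(a = 1L)), "not aligned")
  # homozygous founder still counts once
  g3 <- stats::setNames(c(2L, 0L, 1L), trio$id)
  expect_equal(founder_entry_count(trio, g3), 1L)
})

test_that("candidate filtering applies window, founder and copy rules", {
  st <- small_study(seed = 51)
  fam <- "2"
  vid <- st$truth$functional$variant[1]
  vrow <- match(vid, st$variants$id)
  region <- data.frame(gene = st$variants$gene[vrow],
                       chrom = st$variants$chrom[vrow],
                       center = st$variants$pos[vrow],
                       window_start = max(1, st$variants$pos[vrow] - 5e5),
                       window_end = st$variants$pos[vrow] + 5e5,
                       family = fam, lod = 1.0)
  cands <- filter_candidates(region, st)
  expect_true(vid %in% cands$variant_id)
  row <- cands[cands$variant_id == vid, ]
  expect_gte(row$copies_in_family, 5L)
  expect_lte(row$entering_founders, 2L)

  # copy threshold edge: requiring more copies than present excludes it
  cp <- row$copies_in_family
  expect_false(vid %in%
    filter_candidates(region, st, min_copies = cp + 1L)$variant_id)
  expect_true(vid %in%
    filter_candidates(region, st, min_copies = cp)$variant_id)
  # founder ceiling of 0 excludes everything that entered the family
  expect_equal(nrow(filter_candidates(region, st, max_founders = 0L)), 0L)

  # monotonicity: relaxing either filter never removes a candidate
  strict <- filter_candidates(region, st, max_founders = 1L, min_copies = 8L)
  loose <- filter_candidates(region, st, max_founders = 2L, min_copies = 5L)
  expect_true(all(strict$variant_id %in% loose$variant_id))

  # overlapping windows deduplicate by variant id
  two <- rbind(region, region)
  cc <- collect_candidates(two, st)
  expect_false(any(duplicated(cc$variant_id)))
})

test_that("common variants are excluded from candidacy", {
  st <- small_study(seed = 51)
  # make one variant common in the whole sample
  st$genotypes[, 3] <- rbinom(nrow(st$genotypes), 2, 0.4)
  vrow <- 3
  region <- data.frame(gene = st$variants$gene[vrow],
                       chrom = st$variants$chrom[vrow],
                       center = st$variants$pos[vrow],
                       window_start = max(1, st$variants$pos[vrow] - 5e5),
                       window_end = st$variants$pos[vrow] + 5e5,
                       family = "1", lod = 1.0)
  expect_false(st$variants$id[vrow] %in%
                 filter_candidates(region, st)$variant_id)
})
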