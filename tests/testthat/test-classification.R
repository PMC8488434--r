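# Gene annotation, parental-analysis flag, the clinical rule cascade
# and ISCN/HGVS-style nomenclature rendering.

gene_fixture <- function() {
  data.frame(
    symbol = c("HIGENE", "TSGENE", "RECGENE", "PLAINGENE", "FARGENE"),
    chrom = "chr1",
    start = c(1e6, 3e6, 5e6, 7e6, 20e6),
    end = c(1.2e6, 3.2e6, 5.2e6, 7.2e6, 20.2e6),
    is_disease_gene = c(TRUE, TRUE, TRUE, FALSE, TRUE),
    dosage_mechanism = c("haploinsufficiency", "triplosensitivity",
                         "recessive", "none", "haploinsufficiency"),
    stringsAsFactors = FALSE)
}

mkcall <- function(chrom = "chr1", start = 0.9e6, end = 1.3e6,
                   type = "het_del", inheritance = "de_novo",
                   mosaic_fraction = 1) {
  data.frame(chrom = chrom, start = start, end = end, type = type,
             mean_ratio = if (grepl("del", type)) 0.5 else 1.5,
             mosaic_fraction = mosaic_fraction,
             inheritance = inheritance, stringsAsFactors = FALSE)
}

test_that("gene overlap is any-1-bp intersection", {
  gt <- gene_fixture()
  # gene fully inside the call
  expect_equal(annotate_genes(mkcall(start = 0.9e6, end = 1.3e6), gt)$symbol,
               "HIGENE")
  # call covering an internal slice of the gene (partial overlap) counts
  expect_equal(annotate_genes(mkcall(start = 1.05e6, end = 1.1e6), gt)$symbol,
               "HIGENE")
  # disjoint gene excluded
  expect_equal(nrow(annotate_genes(mkcall(start = 9e6, end = 9.5e6), gt)), 0)
})

test_that("parental-analysis flag follows disease genes and direction-matched dosage", {
  gt <- gene_fixture()
  loss_hi <- mkcall(start = 0.9e6, end = 1.3e6, type = "het_del")
  expect_true(flag_requires_parental_analysis(loss_hi,
                                              annotate_genes(loss_hi, gt)))
  # gain over a haploinsufficiency-only, non-disease gene: no flag
  gt2 <- gt; gt2$is_disease_gene[1] <- FALSE
  gain_hi <- mkcall(start = 0.9e6, end = 1.3e6, type = "dup")
  expect_false(flag_requires_parental_analysis(gain_hi,
                                               annotate_genes(gain_hi, gt2)))
  none <- mkcall(start = 9e6, end = 9.5e6)
  expect_false(flag_requires_parental_analysis(none,
                                               annotate_genes(none, gt)))
})

test_that("the rule cascade reproduces the worked clinical outcomes", {
  gt <- gene_fixture()
  # de novo loss over a haploinsufficient disease gene: pathogenic
  c1 <- mkcall(start = 0.9e6, end = 1.3e6, type = "het_del")
  r1 <- classify_variant(c1, annotate_genes(c1, gt))
  expect_equal(r1$category, "pathogenic")
  expect_true(r1$requires_parental_analysis)
  # de novo loss over a disease gene with uncertain dosage evidence: VUS
  c2 <- mkcall(start = 4.9e6, end = 5.3e6, type = "het_del")
  r2 <- classify_variant(c2, annotate_genes(c2, gt))
  expect_equal(r2$category, "VUS")
  # inherited loss without disease genes: likely benign
  c3 <- mkcall(start = 6.9e6, end = 7.3e6, type = "het_del",
               inheritance = "maternal")
  expect_equal(classify_variant(c3, annotate_genes(c3, gt))$category,
               "likely_benign")
  # inherited loss over a haploinsufficient disease gene: likely pathogenic
  c4 <- mkcall(start = 0.9e6, end = 1.3e6, inheritance = "paternal")
  expect_equal(classify_variant(c4, annotate_genes(c4, gt))$category,
               "likely_pathogenic")
  # ... unless it is an established syndrome region
  syn <- data.frame(chrom = "chr1", start = 0.9e6, end = 1.3e6,
                    type = "het_del")
  expect_equal(classify_variant(c4, annotate_genes(c4, gt),
                                syndrome_regions = syn)$category,
               "pathogenic")
  # known benign region
  ben <- data.frame(chrom = "chr1", start = 6.9e6, end = 7.3e6,
                    type = "het_del")
  expect_equal(classify_variant(c3, annotate_genes(c3, gt),
                                benign_regions = ben)$category, "benign")
  # missing inheritance is an error, never a silent default
  c5 <- mkcall(); c5$inheritance <- NA_character_
  expect_error(classify_variant(c5, annotate_genes(c5, gt)), "inheritance")
})

test_that("every rule-input combination yields exactly one category", {
  gt <- gene_fixture()
  regions <- data.frame(chrom = "chr1", start = 0.5e6, end = 21e6,
                        type = "het_del")
  cats <- c("pathogenic", "likely_pathogenic", "VUS", "likely_benign",
            "benign")
  for (type in c("het_del", "dup"))
    for (inh in c("de_novo", "maternal", "paternal", "biparental"))
      for (span in list(c(0.9e6, 1.3e6), c(2.9e6, 3.3e6), c(4.9e6, 5.3e6),
                        c(6.9e6, 7.3e6), c(9e6, 9.5e6)))
        for (syn in list(NULL, regions))
          for (ben in list(NULL, regions))
            for (rare in c(TRUE, FALSE)) {
              call <- mkcall(start = span[1], end = span[2], type = type,
                             inheritance = inh)
              res <- classify_variant(call, annotate_genes(call, gt),
                                      rare = rare, syndrome_regions = syn,
                                      benign_regions = ben)
              expect_true(res$category %in% cats)
              expect_gt(length(res$rationale), 0)
            }
})

test_that("nomenclature strings match the reporting grammar byte for byte", {
  cb <- example_cytobands()
  ehmt1 <- mkcall(chrom = "chr9", start = 140608441, end = 140673160,
                  type = "het_del")
  expect_identical(
    format_nomenclature(ehmt1, cb),
    "seq[GRCh37/hg19] del(9)(q34.3)dn chr9:g.140608441_140673160del")

  mosaic20q <- mkcall(chrom = "chr20", start = 61942378, end = 62945038,
                      type = "het_del", mosaic_fraction = 0.5)
  expect_identical(
    format_nomenclature(mosaic20q, cb),
    "seq[GRCh37/hg19] del(20)(q13.33)dn chr20:g.61942378_62945038del[0.5]")

  dup18 <- mkcall(chrom = "chr18", start = 42995657, end = 43104692,
                  type = "dup")
  expect_identical(
    format_nomenclature(dup18, cb, build_label = "GRCh37"),
    "seq[GRCh37] dup(18)(q12.3)dn chr18:g.42995657_43104692dup")

  # multi-band span joins first and last band with no separator
  ydel <- mkcall(chrom = "chrY", start = 16e6, end = 30e6,
                 type = "het_del", inheritance = "paternal")
  expect_identical(
    format_nomenclature(ydel, cb),
    "seq[GRCh37/hg19] del(Y)(q11.221q12) chrY:g.16000000_30000000del")

  ehmt1_bad <- mkcall(chrom = "chr2", start = 1, end = 2)
  expect_error(format_nomenclature(ehmt1_bad, cb), "cytoband")
})

test_that("nomenclature round-trips through its parser exactly", {
  cb <- example_cytobands()
  set.seed(17)
  for (k in 1:25) {
    chrom <- sample(c("chr9", "chr20", "chr18"), 1)
    lim <- max(cb$end[cb$chrom == chrom])
    s <- sample.int(lim - 2e6, 1)
    e <- s + sample.int(2e6, 1)
    type <- sample(c("het_del", "hom_del", "dup", "trp"), 1)
    inh <- sample(c("de_novo", "maternal"), 1)
    frac <- sample(c(1, 0.5, 0.3, 0.25), 1)
    call <- mkcall(chrom = chrom, start = s, end = e, type = type,
                   inheritance = inh, mosaic_fraction = frac)
    parsed <- parse_nomenclature(format_nomenclature(call, cb))
    expect_equal(parsed$chrom, chrom)
    expect_equal(parsed$start, s)
    expect_equal(parsed$end, e)
    expect_equal(parsed$type,
                 if (type %in% c("dup", "trp")) "dup" else "del")
    expect_equal(parsed$de_novo, inh == "de_novo")
    expect_equal(parsed$mosaic_fraction, frac)
  }
})

test_that("size rendering matches the clinical report convention", {
  expect_equal(format_cnv_size(140673160 - 140608441 + 1), "64.7 kb")
  expect_equal(format_cnv_size(62945038 - 61942378 + 1), "1.0 Mb")
  expect_equal(format_cnv_size(19300), "19.3 kb")
  expect_equal(format_cnv_size(2.5e6), "2.5 Mb")
})

test_that("cytoband tables read from UCSC format", {
  path <- tempfile(fileext = ".txt")
  writeLines(c("chr9\t140300000\t141213431\tq34.3\tgneg",
               "chr9\t0\t140300000\tq34.2\tgpos50"), path)
  cb <- read_cytoband(path)
  expect_equal(cb$start, c(140300001, 1))  # 0-based to 1-based
  expect_equal(cb$band[1], "q34.3")
})
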