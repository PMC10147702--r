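# Readers/writers for the three tabular/text dialects.

test_that("alignment reader parses features and ranks fragments", {
  tsv <- file.path(tempdir(), "aln.tsv")
  writeLines(c(
    "FeatureId\tRunId\tPrecursorMz\tRT\tCCS\tSN\tHeight\tMS2",
    paste0("F1\trun1\t300.1\t2.5\t150.2\t25\t10000\t",
           "100.1:50 200.2:500 150.0:30 120.5:400 90.0:20 80.0:10"),
    "F2\trun1\t410.2\t4.0\t180.0\t18\t5000\t70.1:5 71.2:4 72.3:3 73.4:2",
    "F3\trun1\t520.9\t6.1\t210.7\t40\t20000\t"), tsv)
  feats <- read_feature_alignment(tsv, "simple_tsv")
  expect_length(feats, 3)
  expect_equal(vapply(feats, function(f) nrow(f$fragments), 0L),
               c(6L, 4L, 0L))
  # rank 1 is the most intense fragment
  expect_equal(feats[[1]]$fragments$mz[feats[[1]]$fragments$rank == 1],
               200.2)
  expect_equal(feats[[1]]$fragments$mz[feats[[1]]$fragments$rank == 2],
               120.5)
})

test_that("alignment reader handles edge cases per contract", {
  tsv <- file.path(tempdir(), "aln2.tsv")
  writeLines("FeatureId\tRunId\tPrecursorMz\tRT\tCCS\tSN\tHeight\tMS2",
             tsv)
  expect_length(read_feature_alignment(tsv), 0)

  writeLines(c("FeatureId\tRunId\tRT\tCCS\tSN\tHeight\tMS2",
               "F1\trun1\t2.5\t150\t25\t1000\t"), tsv)
  expect_error(read_feature_alignment(tsv), "precursor_mz")

  writeLines(c("FeatureId\tRunId\tPrecursorMz\tRT\tCCS\tSN\tHeight\tMS2",
               "F1\trun1\t300\t2.5\t150\t25\t1000\t100.1:50 oops 200.2:30"),
             tsv)
  expect_warning(feats <- read_feature_alignment(tsv), "unparsable")
  expect_equal(nrow(feats[[1]]$fragments), 2)
})

test_that("alignment reader accepts an MS-DIAL-style header", {
  tsv <- file.path(tempdir(), "msdial.tsv")
  writeLines(c(paste("Alignment ID", "Spectrum reference file name",
                     "Average Mz", "Average Rt(min)", "CCS", "S/N average",
                     "Height", "MS/MS spectrum", sep = "\t"),
               "12\tsampleA\t300.5\t3.3\t161.0\t22\t8000\t95.1:100 110.2:40"),
             tsv)
  feats <- read_feature_alignment(tsv, "msdial_alignment")
  expect_length(feats, 1)
  expect_equal(feats[[1]]$feature_id, "12")
  expect_equal(feats[[1]]$run_id, "sampleA")
  expect_equal(nrow(feats[[1]]$fragments), 2)
})

test_that("intensity ties in fragment ranking break by ascending m/z", {
  f <- rank_fragments(data.frame(mz = c(200, 100, 150),
                                 intensity = c(50, 50, 80)))
  expect_equal(f$mz, c(150, 100, 200))
  expect_equal(f$rank, 1:3)
})

test_that("XIC report round-trips and groups by (group, run)", {
  gs <- list(make_group("G1", fragments = make_fragments(5)),
             make_group("G2", fragments = make_fragments(5)))
  p <- file.path(tempdir(), "xic.csv")
  write_xic_report(gs, p)
  expect_equal(length(readLines(p)), 13)  # header + 2 x (1 + 5)
  back <- read_xic_report(p)
  expect_length(back, 2)
  expect_equal(vapply(back, function(g) nrow(g$fragments), 0L), c(5L, 5L))
  g1 <- back[[which(vapply(back, `[[`, "", "group_id") == "G1")]]
  expect_equal(g1$precursor$rt, gs[[1]]$precursor$rt)
  expect_equal(g1$fragments$area, gs[[1]]$fragments$area)

  # same group in 3 runs -> 3 peak-groups sharing group_id
  gs3 <- lapply(c("run1", "run2", "run3"), function(r)
    make_group("G1", run = r))
  write_xic_report(gs3, p)
  back3 <- read_xic_report(p)
  expect_length(back3, 3)
  expect_equal(unique(vapply(back3, `[[`, "", "group_id")), "G1")
})

test_that("missing numeric cells are flagged missing, never 0", {
  p <- file.path(tempdir(), "xicmiss.csv")
  hdr <- paste("GroupId,ReplicateName,Label,PartnerGroupId,IsPrecursor,Mz",
               "ExpectedIntensity,Area,Height,Fwhm,RetentionTime",
               "MassErrorPPM,ExpectedRT,ExpectedCCS,ObservedCCS",
               "SignalToNoise", sep = ",")
  writeLines(c(hdr,
               "G1,run1,target,,TRUE,300,NA,5e4,1000,0.1,5,1,5,150,150,30",
               "G1,run1,target,,FALSE,90,600,1.5e3,#N/A,0.1,5,1,5,150,150,NA",
               "G1,run1,target,,FALSE,120,400,1e3,NaN,0.1,5,1,5,150,150,NA"),
             p)
  g <- read_xic_report(p)[[1]]
  expect_true(all(is.na(g$fragments$height)))
  expect_false(any(g$fragments$height %in% 0))
})

test_that("XIC groups without exactly one precursor row are an error", {
  gs <- list(make_group("G1"))
  p <- file.path(tempdir(), "xicbad.csv")
  write_xic_report(gs, p)
  lines <- readLines(p)
  writeLines(c(lines, sub("TRUE", "TRUE", lines[2])), p)  # duplicate precursor
  expect_error(read_xic_report(p), "G1")
})

test_that("MSP library reader parses the 64-standard library", {
  lib <- read_library_msp(path_to_library())
  expect_length(lib, 64)
  nm <- vapply(lib, `[[`, "", "name")
  f16dp <- lib[[grep("F16DP", nm)]]
  expect_equal(f16dp$precursor_mz, 338.98877)
  expect_equal(f16dp$rt, 4.95)
  expect_equal(f16dp$ccs, 155.00)
  expect_equal(nrow(f16dp$fragments), 6)
  # normalized intensities kept alongside raw
  expect_equal(max(f16dp$fragments$rel_intensity), 100)
  expect_true(all(lib[[1]]$fragments$intensity > 0))
})

test_that("MSP reader edge cases: empty file, missing precursor, round trip", {
  p <- file.path(tempdir(), "empty.msp")
  writeLines(character(), p)
  expect_length(read_library_msp(p), 0)

  writeLines(c("NAME: mystery", "Num Peaks: 1", "100.0 50", "",
               "NAME: good", "PRECURSORMZ: 200.1", "Num Peaks: 0"), p)
  expect_warning(lib <- read_library_msp(p), "skipped")
  expect_length(lib, 1)
  expect_equal(lib[[1]]$name, "good")

  orig <- read_library_msp(path_to_library())
  p2 <- file.path(tempdir(), "rt.msp")
  write_library_msp(orig, p2)
  back <- read_library_msp(p2)
  expect_equal(vapply(back, `[[`, "", "name"),
               vapply(orig, `[[`, "", "name"))
  expect_equal(vapply(back, `[[`, 0, "precursor_mz"),
               vapply(orig, `[[`, 0, "precursor_mz"))
  expect_equal(back[[3]]$fragments$mz, orig[[3]]$fragments$mz)
})

test_that("transition list: row arithmetic, empty input, round trip", {
  tg <- make_feature("T1", frag_int = c(900, 700, 500, 300, 200, 100))
  pr <- pair_targets(list(tg, make_feature("T2", mz = 310, rt = 8.5,
                                           frag_int = c(800, 600, 400,
                                                        250, 150, 80))))
  dec <- generate_decoys(pr$pairs, seed = 3)
  tr <- transition_table(list(tg), dec$decoys[1])
  expect_equal(nrow(tr), 14)  # 2 precursors + 12 products
  expect_equal(sum(tr$is_precursor), 2)

  p <- file.path(tempdir(), "trans.csv")
  write_transition_list(tr, p)
  back <- read_transition_list(p)
  expect_equal(back$group_id, tr$group_id)
  expect_equal(back$mz, tr$mz, tolerance = 1e-12)
  expect_equal(back$is_precursor, tr$is_precursor)
  expect_equal(back$partner_id, tr$partner_id)
  # fragment drift-time offsets carried per transition
  frg <- !back$is_precursor
  expect_equal(back$dt_offset[frg],
               mobility_offset(back$precursor_mz[frg], back$mz[frg]))

  write_transition_list(transition_table(list()), p)
  expect_equal(length(readLines(p)), 1)  # header only
  expect_equal(nrow(read_transition_list(p)), 0)
})

test_that("result writer emits tagged threshold and annotation files", {
  ft <- data.frame(score_threshold = c(0.9, 0.5, 0.1),
                   fdr = c(0, 0.01, 0.4))
  ann <- data.frame(metabolite = "x", run_id = "run1", score = 0.2,
                    mass_error_ppm = 3, rt_error = 0.1,
                    ccs_error_pct = 0.2, n_fragments = 3,
                    level = "RT-CCS-DIA", passed = FALSE)
  files <- write_results(ann, ft, file.path(tempdir(), "res"), "mydata")
  expect_true(grepl("PeakDecoder-FDR-thresholds_mydata.csv",
                    files["fdr_thresholds"]))
  expect_equal(length(readLines(files["fdr_thresholds"])), 4)
  back <- utils::read.csv(files["annotations"])
  expect_equal(nrow(back), 1)
  expect_false(back$passed)  # non-passing rows stay present, flagged false
})
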