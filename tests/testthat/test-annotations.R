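test_that("create_annotation validates box, bounds, class and confidence", {
  ann <- create_annotation(bounding_box(3.1, 4.0, 2.0, 5.5), "Robin",
                           "RAHORA_20220415_063000.wav",
                           clip_duration = 15, nyquist = 12)
  expect_identical(ann$class_label, "Robin")
  expect_identical(ann$confidence, 100L)
  expect_match(ann$date_time,
               "^\\d{4}-\\d{2}-\\d{2}T\\d{2}:\\d{2}:\\d{2}[+-]\\d{4}$")

  expect_error(bounding_box(4, 4, 2, 5), "t_start")
  expect_error(create_annotation(bounding_box(3, 4, 2, 5), "Robin", "f.wav",
                                 confidence = 101, clip_duration = 15,
                                 nyquist = 12), "confidence")
  expect_error(create_annotation(bounding_box(3, 4, 2, 5), "", "f.wav",
                                 clip_duration = 15, nyquist = 12),
               "class_label")
  expect_error(create_annotation(bounding_box(3, 16, 2, 5), "Robin", "f.wav",
                                 clip_duration = 15, nyquist = 12),
               "clip")
  expect_error(create_annotation(bounding_box(3, 4, 2, 13), "Robin", "f.wav",
                                 clip_duration = 15, nyquist = 12),
               "Nyquist")
})

test_that("save writes labels_<username>.csv with labels_tmp fallback", {
  dir <- withr::local_tempdir()
  set <- make_test_set(list(
    list(t0 = 1, t1 = 2, f0 = 2, f1 = 4, class = "Robin", file = "a.wav")))
  p1 <- save_annotations(set, dir, username = "annotator1")
  expect_identical(basename(p1), "labels_annotator1.csv")
  expect_identical(basename(dirname(p1)), "labels")
  p2 <- save_annotations(set, dir, username = "")
  expect_identical(basename(p2), "labels_tmp.csv")
  expect_true(file.exists(p2))
})

test_that("save then load round-trips every field including non-ASCII", {
  dir <- withr::local_tempdir()
  set <- annotation_set()
  set.seed(7)
  for (i in 1:50) {
    t0 <- runif(1, 0, 13)
    f0 <- runif(1, 0, 10)
    set <- add_annotation(set, create_annotation(
      bounding_box(t0, t0 + runif(1, 0.1, 2), f0, f0 + runif(1, 0.2, 1.9)),
      class_label = sample(c("Robin", "Wren", "Blackbird", "Meadow Pipit"), 1),
      file_name = sample(c("a.wav", "b.wav"), 1),
      confidence = sample(0:100, 1), labeller = "annótator",
      call_type = sample(c("", "song", "call"), 1),
      notes = "café ♪ with, comma and \"quotes\"",
      clip_duration = 15, nyquist = 12))
  }
  path <- save_annotations(set, dir, "rt")
  back <- load_annotations(path)
  expect_equal(back$records, set$records)
})

test_that("loading tolerates a UTF-8 BOM and defaults optional columns", {
  dir <- withr::local_tempdir()
  body <- paste(
    "date_time,file_name,start_time,end_time,start_freq,end_freq,class_label",
    "2022-04-15T06:30:00+0100,a.wav,1.5,2.5,2,4,Robin",
    "2022-04-15T06:31:00+0100,a.wav,3,4,1,2,Wren",
    sep = "\n")
  plain <- file.path(dir, "plain.csv")
  writeLines(body, plain, useBytes = TRUE)
  bom <- file.path(dir, "bom.csv")
  con <- file(bom, "wb")
  writeBin(as.raw(c(0xEF, 0xBB, 0xBF)), con)
  writeBin(charToRaw(paste0(body, "\n")), con)
  close(con)

  a <- load_annotations(plain)
  b <- load_annotations(bom)
  expect_equal(a$records, b$records)
  expect_identical(a$records$confidence, c(100L, 100L))
  expect_identical(a$records$labeller, c("", ""))
  # parsed zone offsets are preserved verbatim, never converted
  expect_identical(a$records$date_time[1], "2022-04-15T06:30:00+0100")
})

test_that("schema and numeric errors are reported precisely", {
  dir <- withr::local_tempdir()
  bad <- file.path(dir, "bad.csv")
  writeLines(paste(
    "date_time,file_name,start_time,end_time,end_freq,class_label",
    "2022-01-01T00:00:00+0000,a.wav,1,2,4,Robin", sep = "\n"), bad)
  expect_error(load_annotations(bad), "start_freq")

  bad2 <- file.path(dir, "bad2.csv")
  writeLines(paste(
    "date_time,file_name,start_time,end_time,start_freq,end_freq,class_label",
    "2022-01-01T00:00:00+0000,a.wav,1,2,2,4,Robin",
    "2022-01-01T00:00:00+0000,a.wav,1,oops,2,4,Wren", sep = "\n"), bad2)
  expect_error(load_annotations(bad2), "end_time.*row 2")
})

test_that("edit updates one record atomically and respects immutability", {
  set <- make_test_set(list(
    list(t0 = 1, t1 = 2, f0 = 2, f1 = 4, class = "Unknown", file = "a.wav"),
    list(t0 = 5, t1 = 6, f0 = 1, f1 = 3, class = "Robin", file = "a.wav")))
  out <- edit_annotation(set, 1, list(class_label = "Wren"))
  expect_identical(out$records$class_label, c("Wren", "Robin"))
  expect_identical(length(out), 2L)

  expect_error(edit_annotation(set, 1, list(end_time = 0.5)), "start_time")
  # failed edit leaves the set unchanged (validated before assignment)
  expect_error(set2 <- edit_annotation(set, 1, list(end_time = 0.5)))
  expect_identical(set$records$end_time[1], 2)

  expect_error(edit_annotation(set, 999, list(class_label = "X")), "999")
  expect_error(edit_annotation(set, 1, list(file_name = "b.wav")),
               "not editable")
})

test_that("delete removes exactly one record and keeps ids stable", {
  set <- make_test_set(list(
    list(t0 = 1, t1 = 2, f0 = 2, f1 = 4, class = "A", file = "a.wav"),
    list(t0 = 2, t1 = 3, f0 = 2, f1 = 4, class = "B", file = "a.wav"),
    list(t0 = 3, t1 = 4, f0 = 2, f1 = 4, class = "C", file = "a.wav")))
  out <- delete_annotation(set, 2)
  expect_identical(out$records$id, c(1L, 3L))
  expect_identical(out$records$class_label, c("A", "C"))
  expect_error(delete_annotation(out, 2), "no annotation")
  only <- delete_annotation(delete_annotation(out, 1), 3)
  expect_identical(length(only), 0L)
})

test_that("filters combine by conjunction with inclusive confidence bound", {
  set <- make_test_set(list(
    list(t0 = 1, t1 = 2, f0 = 2, f1 = 4, class = "Blackbird", file = "a.wav",
         conf = 60),
    list(t0 = 2, t1 = 3, f0 = 2, f1 = 4, class = "Blackbird", file = "a.wav",
         conf = 80),
    list(t0 = 3, t1 = 4, f0 = 2, f1 = 4, class = "Blackbird", file = "b.wav",
         conf = 95),
    list(t0 = 4, t1 = 5, f0 = 2, f1 = 4, class = "Robin", file = "a.wav"),
    list(t0 = 5, t1 = 6, f0 = 2, f1 = 4, class = "Robin", file = "b.wav")))
  expect_identical(length(filter_annotations(set)), 5L)
  expect_identical(length(filter_annotations(set, class_label = "Blackbird")),
                   3L)
  expect_identical(length(filter_annotations(set, min_confidence = 80)), 4L)
  expect_identical(length(filter_annotations(set, class_label = "Blackbird",
                                             file_name = "a.wav")), 2L)
  expect_identical(length(filter_annotations(set, time_window = c(4.5, 10))),
                   2L)
})

test_that("summaries cover zero-label files and cross-check the filters", {
  files <- c("fileA.wav", "fileB.wav", "fileC.wav")
  empty <- summarize_annotations(annotation_set(), files)
  expect_identical(nrow(empty), 3L)
  expect_true(all(empty$n_labels == 0))

  set <- make_test_set(list(
    list(t0 = 1, t1 = 2, f0 = 2, f1 = 4, class = "Robin", file = "fileA.wav"),
    list(t0 = 2, t1 = 3, f0 = 2, f1 = 4, class = "Robin", file = "fileA.wav"),
    list(t0 = 3, t1 = 4, f0 = 2, f1 = 4, class = "Wren", file = "fileA.wav"),
    list(t0 = 1, t1 = 2, f0 = 2, f1 = 4, class = "Wren", file = "fileB.wav")))
  tab <- summarize_annotations(set, files)
  expect_identical(tab$n_labels, c(3L, 1L, 0L))
  expect_identical(tab$Robin, c(2L, 0L, 0L))
  expect_identical(tab$Wren, c(1L, 1L, 0L))
  expect_equal(rowSums(tab[, c("Robin", "Wren")]),
               as.numeric(tab$n_labels), ignore_attr = TRUE)
  expect_identical(sum(tab$n_labels), length(set))
  for (cl in c("Robin", "Wren")) {
    expect_identical(sum(tab[[cl]]),
                     length(filter_annotations(set, class_label = cl)))
  }
})
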