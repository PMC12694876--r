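# Reading, validation and cascade assembly.

test_that("event streams round-trip through JSONL and CSV", {
  cfg <- scenario_config(n_cascades = 40, n_authors = 30, seed = 2)
  sim <- gen_event_stream(cfg)
  for (ext in c(".jsonl", ".csv")) {
    path <- withr::local_tempfile(fileext = ext)
    write_events(sim$events, path)
    back <- read_events(path)
    expect_equal(nrow(back), nrow(sim$events))
    for (col in names(sim$events)) {
      expect_equal(back[[col]], sim$events[[col]], tolerance = 1e-15,
                   ignore_attr = TRUE, label = paste(ext, col))
    }
  }
})

test_that("score policies renormalize or reject off-simplex rows", {
  ev <- hand_events()
  ev[2, paste0("score_", emotion_labels())] <-
    ev[2, paste0("score_", emotion_labels())] * 0.8
  expect_error(validate_events(ev, score_policy = "strict"), "sum to 1")
  expect_message(fixed <- validate_events(ev, score_policy = "renormalize"),
                 "renormalized")
  sums <- rowSums(as.matrix(fixed[paste0("score_", emotion_labels())]))
  expect_true(all(abs(sums - 1) < 1e-12))
  # all-zero scores are rejected under any policy
  ev0 <- hand_events()
  ev0[1, paste0("score_", emotion_labels())] <- 0
  expect_error(validate_events(ev0, score_policy = "renormalize"), "all-zero")
})

test_that("schema violations are reported by name and line", {
  ev <- hand_events()
  expect_error(validate_events(ev[setdiff(names(ev), "author_id")]),
               "author_id")
  ev$score_boredom <- 0.1
  expect_error(validate_events(ev), "score_boredom")

  path <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(c('{"event_id": "a"}', "{broken json"), path)
  expect_error(read_events(path), "line.*2")
})

test_that("author tables are validated on read", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("author_id,followers,friends,statuses,likes,verified",
               "u1,10,5,100,2,true",
               "u2,0,0,1,0,0",
               "u3,99,1,50,7,1"), path)
  au <- read_authors(path)
  expect_identical(au$verified, c(TRUE, FALSE, TRUE))

  writeLines(c("author_id,followers,friends,statuses,likes,verified",
               "u1,10,5,100,2,true",
               "u1,4,5,10,2,false"), path)
  expect_error(read_authors(path), "duplicate")

  writeLines("author_id,followers,friends,statuses,likes,verified", path)
  expect_warning(empty <- read_authors(path), "empty")
  expect_equal(nrow(empty), 0)
})

test_that("cascades assemble with the window and orphan rules", {
  ev <- hand_events() # t1 with reshares at 10 and 160 s
  extra <- ev[1, ]
  extra$event_id <- "t2" # root that is never reshared
  extra$time_s <- 5
  late <- ev[2, ]
  late$event_id <- "t1_r3"
  late$time_s <- 22 * 86400 # outside the 21-day window
  orphan <- ev[2, ]
  orphan$event_id <- "zz"
  orphan$root_id <- "missing_root"
  all_ev <- dplyr::bind_rows(ev, extra, late, orphan)

  expect_message(cas <- build_cascades(all_ev, event_start_s = 0),
                 "dropped")
  expect_equal(nrow(cas), 1) # unreshared root excluded
  expect_equal(cas$size, 3L) # late reshare dropped, the other two kept
  expect_equal(cas$cascade_id, "t1")
  expect_equal(attr(cas, "dropped")[["outside_window"]], 1L)
  expect_equal(attr(cas, "dropped")[["orphan_retweets"]], 1L)
  expect_equal(attr(cas, "dropped")[["rootless_roots"]], 1L)

  # a root plus three reshares is a cascade of four posts
  r3 <- ev[2, ]
  r3$event_id <- "t1_r3"
  r3$time_s <- 200
  cas4 <- suppressMessages(build_cascades(dplyr::bind_rows(ev, r3), 0))
  expect_equal(cas4$size, 4L)
})

test_that("simultaneous reshares are ordered by event id", {
  ev <- hand_events()
  ev$time_s <- c(0, 50, 50) # tie between t1_r1 and t1_r2
  ev$event_id <- c("t1", "t1_rB", "t1_rA")
  ev$root_id <- c("", "t1", "t1")
  cas <- build_cascades(ev, event_start_s = 0)
  expect_identical(cas$retweets[[1]]$event_id, c("t1_rA", "t1_rB"))
  expect_identical(inter_event_delays(c(0, cas$retweets[[1]]$time_s)), c(50, 0))
})

test_that("assembly conserves events and is idempotent", {
  cfg <- scenario_config(n_cascades = 150, n_authors = 80, seed = 8)
  sim <- gen_event_stream(cfg)
  cas <- build_cascades(sim$events, cfg$event_start_s, cfg$window_days)
  expect_equal(sum(cas$size), nrow(sim$events))

  flat <- cascade_events(cas)
  cas2 <- build_cascades(flat, cfg$event_start_s, cfg$window_days)
  expect_equal(dplyr::arrange(as.data.frame(cas2), cascade_id),
               dplyr::arrange(as.data.frame(cas), cascade_id),
               ignore_attr = TRUE)
})

test_that("size filters mirror the analysis subsets", {
  f <- tibble::tibble(size = c(2L, 3L, 6L), id = 1:3)
  expect_equal(filter_by_size(f, 3)$id, 2:3)
  expect_equal(filter_by_size(f, 2), f) # identity at the base threshold
  # "at least five reshares" is the size >= 6 subset
  expect_equal(filter_by_size(f, 6)$size, 6L)
  expect_error(filter_by_size(f, 1), ">= 2")
})
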