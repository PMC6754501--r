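test_that("wire protocol: bit-exact round trip and corruption errors", {
  set.seed(4)
  for (i in 1:5) {
    img <- matrix(sample(0:65535, 64 * 64, TRUE), 64, 64)
    ts <- sample(1e12, 1)
    b <- encode_frame_message(img, i, 10L + i, i %% 3L, (i + 1L) %% 3L, ts)
    m <- decode_frame_message(b)
    expect_identical(m$image, img)
    expect_identical(m$channel_id, i)
    expect_identical(m$sequence_index, as.numeric(10 + i))
    expect_identical(m$timestamp_ns, ts)
  }
  img <- matrix(0L, 8, 8)
  b <- encode_frame_message(img)
  expect_equal(length(encode_frame_message(matrix(0L, 512, 512))),
               29 + 2 * 512^2)
  bad <- b; bad[1] <- as.raw(0)
  expect_error(decode_frame_message(bad), "magic")
  expect_error(decode_frame_message(b[-length(b)]), "length mismatch")
  badv <- b; badv[5] <- as.raw(9)
  expect_error(decode_frame_message(badv), "version")
  expect_error(decode_frame_message(b[1:10]), "header")
})

test_that("frame grouping: complete sets, gap handling, channel independence", {
  mk <- function(ch, seq) list(image = matrix(seq, 4, 4), channel_id = ch,
                               sequence_index = seq,
                               angle_index = (seq %% 9L) %/% 3L,
                               phase_index = seq %% 3L,
                               timestamp_ns = 1e6 + seq * 1000)
  g <- frame_grouper()
  sets <- Filter(Negate(is.null), lapply(0:17, function(s) grouper_feed(g, mk(1L, s))))
  expect_length(sets, 2)
  expect_s3_class(sets[[1]], "raw_sim_set")
  expect_equal(grouper_stats(g)$discarded_sets, 0L)
  # frame 7 (seq 6) of the first set missing: set 1 dropped, set 2 intact
  g2 <- frame_grouper()
  seqs <- setdiff(0:17, 6L)
  sets2 <- Filter(Negate(is.null), lapply(seqs, function(s) grouper_feed(g2, mk(1L, s))))
  expect_length(sets2, 1)
  expect_equal(grouper_stats(g2)$discarded_sets, 1L)
  # conservation: frames in = 9*sets + partial/orphaned frames
  st <- grouper_stats(g2)
  expect_identical(length(seqs),
                   9L * length(sets2) + st$frames_in_partial + st$frames_pending)
  # interleaved channels group independently
  g3 <- frame_grouper()
  n3 <- 0L
  for (s in 0:8) for (ch in 1:2)
    if (!is.null(grouper_feed(g3, mk(ch, s)))) n3 <- n3 + 1L
  expect_identical(n3, 2L)
})

test_that("ring buffer: eviction, FIFO, empty pop, conservation property", {
  rb <- ring_buffer(2)
  ring_push(rb, "a"); ring_push(rb, "b"); ring_push(rb, "c")
  expect_identical(ring_pop(rb), "b")
  expect_identical(ring_pop(rb), "c")
  expect_identical(rb$drop_count, 1L)
  expect_true(is_ring_empty(ring_pop(rb)))
  expect_error(ring_buffer(0), "at least 1")
  # randomized operation sequence against a reference deque oracle
  set.seed(77)
  rb <- ring_buffer(5)
  oracle <- list()
  o_drop <- 0L
  for (i in 1:10000) {
    if (stats::runif(1) < 0.55) {
      ring_push(rb, i)
      oracle[[length(oracle) + 1L]] <- i
      if (length(oracle) > 5) { oracle <- oracle[-1]; o_drop <- o_drop + 1L }
    } else {
      got <- ring_pop(rb)
      if (length(oracle)) {
        expect_identical(got, oracle[[1]])
        oracle <- oracle[-1]
      } else expect_true(is_ring_empty(got))
    }
    st <- ring_stats(rb)
    expect_identical(st$pushed, st$popped + st$drop_count + st$occupancy)
  }
  expect_identical(rb$drop_count, o_drop)
  expect_identical(rb$count, length(oracle))
})

test_that("affine registration recovers known transforms to < 0.05 px", {
  otf <- fix_otf256()
  set.seed(3)
  ctr <- cbind(stats::runif(12, 40, 216), stats::runif(12, 40, 216))
  ph <- make_phantom("points", c(256L, 256L), centers = ctr)
  ref <- simflow:::otf_blur(ph$image, otf); ref[ref < 0] <- 0
  expect_error(estimate_registration_affine(ref * 0 + 1e-9, ref), "centroids")
  # identity
  est0 <- estimate_registration_affine(ref, ref)
  expect_lt(est0$rms_residual, 1e-6)
  expect_equal(est0$matrix, cbind(diag(2), c(0, 0)), tolerance = 1e-6)
  # pure shift (3, -1.5) px
  mv <- warp_affine(ref, cbind(diag(2), c(3, -1.5)))
  est1 <- estimate_registration_affine(ref, mv)
  expect_lt(est1$rms_residual, 0.05)
  expect_equal(est1$matrix[, 3], c(-3, 1.5), tolerance = 0.05)
  # 0.5 deg rotation about the image centre plus shift
  th <- 0.5 * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  tr <- cbind(R, c(2, 1) + 127.5 - R %*% c(127.5, 127.5))
  est2 <- estimate_registration_affine(ref, warp_affine(ref, tr))
  expect_lt(est2$rms_residual, 0.05)
  # applying the estimated transform aligns the bead positions (pixel
  # intensities smooth under double bilinear warping, so the contract
  # is geometric: residual centroid distance)
  back <- apply_registration(warp_affine(ref, tr), est2)
  cb <- simflow:::detect_bead_centroids(back)
  cr <- simflow:::detect_bead_centroids(ref)
  res <- vapply(seq_len(nrow(cr)), function(i)
    min(sqrt((cb[, 1] - cr[i, 1])^2 + (cb[, 2] - cr[i, 2])^2)), 0)
  expect_lt(sqrt(mean(res^2)), 0.1)
  # inverse round trip
  inv <- invert_affine(est2)
  expect_equal(inv[, 1:2] %*% est2$matrix[, 1:2], diag(2), tolerance = 1e-9)
})

test_that("registration brings two-channel beads below 0.2 px rms", {
  otf <- fix_otf128()
  set.seed(8)
  ctr <- cbind(stats::runif(8, 25, 103), stats::runif(8, 25, 103))
  ph <- make_phantom("points", c(128L, 128L), centers = ctr)
  truth <- cbind(matrix(c(1.001, 0.002, -0.002, 0.999), 2), c(2.3, -1.2))
  msgs <- simulate_multichannel_sequence(list(ph, ph),
                                         list(default_illumination(otf),
                                              default_illumination(otf)),
                                         list(otf, otf), 1L,
                                         misregistration = list(NULL, truth))
  wf <- function(ch) Reduce(`+`, lapply(Filter(function(m) m$channel_id == ch,
                                               msgs), `[[`, "image")) / 9
  est <- estimate_registration_affine(wf(1), wf(2))
  c2 <- simflow:::detect_bead_centroids(apply_registration(wf(2), est))
  c1 <- simflow:::detect_bead_centroids(wf(1))
  # match and measure residual distance
  res <- vapply(seq_len(nrow(c1)), function(i)
    min(sqrt((c2[, 1] - c1[i, 1])^2 + (c2[, 2] - c1[i, 2])^2)), 0)
  expect_lt(sqrt(mean(res^2)), 0.2)
})

test_that("live pipeline: reconstructs all sets, accounts for every frame", {
  otf <- fix_otf128()
  ph <- make_phantom("bead_clusters", c(128L, 128L), seed = 6, n = 10)
  il <- default_illumination(otf)
  msgs <- simulate_multichannel_sequence(list(ph), list(il), list(otf),
                                         n_timepoints = 4L,
                                         photons_scale = 800, seed = 2)
  fake_ns <- local({ t <- 0; function() { t <<- t + 1e6; t } })
  got <- list()
  rep <- run_live_pipeline(msgs, il, otf, sink = function(r)
    got[[length(got) + 1]] <<- r, clock = fake_ns)
  expect_identical(rep$n_reconstructed, 4L)
  expect_identical(rep$drops, 0L)
  expect_length(rep$latency_ns, 4)
  expect_length(got, 4)
  expect_identical(dim(got[[1]]$sim), c(256L, 256L))
  # frame conservation end to end
  expect_identical(length(msgs),
                   9L * (rep$n_reconstructed + rep$drops) +
                     rep$grouping$frames_in_partial + rep$grouping$frames_pending)
  expect_error(run_live_pipeline(msgs, NULL, otf), "fit_channel_params")
})

test_that("slow consumer with small ring: oldest sets dropped, no stall", {
  otf <- fix_otf128()
  ph <- make_phantom("bead_clusters", c(128L, 128L), seed = 6, n = 10)
  il <- default_illumination(otf)
  msgs <- simulate_multichannel_sequence(list(ph), list(il), list(otf),
                                         n_timepoints = 6L,
                                         photons_scale = 800, seed = 2)
  rep <- run_live_pipeline(msgs, il, otf, capacity = 3L,
                           consume_every = 10000L)
  expect_identical(rep$n_reconstructed, 3L)  # the newest three
  expect_identical(rep$drops, 3L)            # the oldest three evicted
  expect_identical(length(msgs), 9L * (rep$n_reconstructed + rep$drops))
})

test_that("live and offline reconstructions of archived raw data agree bit-for-bit", {
  otf <- fix_otf128()
  ph <- make_phantom("bead_clusters", c(128L, 128L), seed = 6, n = 10)
  il <- default_illumination(otf, modulation = 0.9)
  msgs <- simulate_multichannel_sequence(list(ph), list(il), list(otf),
                                         n_timepoints = 3L,
                                         photons_scale = 600, seed = 5)
  dir <- tempfile("archive")
  on.exit(unlink(dir, recursive = TRUE))
  # feed encoded wire messages so the live path sees the same integer
  # pixels that the archive stores
  msgs <- lapply(msgs, function(m)
    encode_frame_message(m$image, m$channel_id, m$sequence_index,
                         m$angle_index, m$phase_index, m$timestamp_ns))
  live <- list()
  rep <- run_live_pipeline(msgs, il, otf,
                           sink = function(r) live[[length(live) + 1]] <<- r$sim,
                           archive_dir = dir)
  sets <- read_raw_stack(file.path(dir, "raw_channel_1.tif"))
  offline <- reconstruct_batch(sets, il, otf)
  expect_length(offline, 3)
  for (i in 1:3) expect_identical(live[[i]], offline[[i]]$sim)
})

test_that("frames survive a real localhost TCP link bit-exactly", {
  msgs <- lapply(1:3, function(i)
    list(image = matrix(sample(0:65535, 32 * 32, TRUE), 32, 32),
         channel_id = 1L, sequence_index = i - 1L,
         angle_index = (i - 1L) %/% 3L, phase_index = (i - 1L) %% 3L,
         timestamp_ns = i * 1e6))
  port <- 30000L + sample(2000L, 1)
  srv <- serverSocket(port)
  on.exit(close(srv), add = TRUE)
  cl <- socketConnection("127.0.0.1", port, blocking = FALSE, open = "a+b")
  on.exit(close(cl), add = TRUE)
  con <- socketAccept(srv, blocking = TRUE, open = "a+b", timeout = 10)
  on.exit(close(con), add = TRUE)
  for (m in msgs) {
    write_framed_message(cl, encode_frame_message(m$image, m$channel_id,
                                                  m$sequence_index,
                                                  m$angle_index, m$phase_index,
                                                  m$timestamp_ns))
    flush(cl)
    got <- decode_frame_message(read_framed_message(con))
    expect_identical(got$image, m$image)
    expect_identical(got$timestamp_ns, m$timestamp_ns)
  }
})
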