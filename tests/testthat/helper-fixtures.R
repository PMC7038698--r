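# Fixture builders and independent brute-force oracles used across the suite.

event_line <- function(time, sensor, message, annotation = NULL,
                       date = "2012-07-18") {
  line <- paste(date, time, sensor, message)
  if (!is.null(annotation)) line <- paste(line, annotation)
  line
}

# A small annotated log: one Bathe instance with five interior events.
bathe_fixture_lines <- function() {
  c(
    event_line("13:47:00.00", "M012", "ON", "Bathe begin"),
    event_line("13:47:01.00", "M012", "OFF"),
    event_line("13:47:02.00", "D002", "OPEN"),
    event_line("13:47:03.00", "D002", "CLOSE"),
    event_line("13:47:04.00", "M013", "ON"),
    event_line("13:47:05.00", "T101", "21.5"),
    event_line("13:47:06.00", "M012", "OFF", "Bathe end")
  )
}

# Random annotated stream: `k` instances over `sensors`, uniform labels.
random_stream_lines <- function(k = 3, sensors = c("M001", "M002", "D001"),
                                labels = c("Cook", "Sleep")) {
  t <- 0
  stamp <- function() {
    t <<- t + sample(1:3, 1)
    sprintf("%02d:%02d:%02d.00", t %/% 3600, (t %/% 60) %% 60, t %% 60)
  }
  lines <- character(0)
  for (i in seq_len(k)) {
    lab <- sample(labels, 1)
    lines <- c(lines, event_line(stamp(), sensors[1], "OFF",
                                 paste(lab, "begin")))
    for (j in seq_len(sample(3:10, 1))) {
      s <- sample(sensors, 1)
      msg <- sample(c("ON", "OFF", "OPEN", "CLOSE"), 1)
      lines <- c(lines, event_line(stamp(), s, msg))
    }
    lines <- c(lines, event_line(stamp(), sensors[1], "OFF",
                                 paste(lab, "end")))
  }
  lines
}

# Oracle: per-label linear scan extracting begin/end spans, then a plain
# time-window filter. Independent of segment_activity_instances().
brute_force_spans <- function(events) {
  out <- list()
  for (lab in unique(stats::na.omit(events$activity))) {
    rows <- which(!is.na(events$activity) & events$activity == lab)
    open <- c()
    for (r in rows) {
      if (events$marker[r] == "begin") {
        open <- c(open, r)
      } else if (length(open) > 0) {
        b <- open[length(open)]
        open <- open[-length(open)]
        out[[length(out) + 1]] <- list(
          label = lab, begin_row = b,
          rows = which(events$timestamp >= events$timestamp[b] &
                         events$timestamp <= events$timestamp[r]))
      }
    }
  }
  out[order(vapply(out, `[[`, numeric(1), "begin_row"))]
}

# Oracle: plain double-loop activation tally.
brute_force_counts <- function(instance_events, vocabulary) {
  counts <- setNames(integer(length(vocabulary)), vocabulary)
  for (i in seq_len(nrow(instance_events))) {
    s <- instance_events$sensor_id[i]
    msg <- toupper(instance_events$message[i])
    if (s %in% vocabulary && msg %in% c("ON", "OPEN")) {
      counts[s] <- counts[s] + 1L
    }
  }
  counts
}

# Oracle: one-vs-rest metrics straight from the definitions, one class at a
# time with scalar loops.
brute_force_ovr <- function(m, k) {
  total <- sum(m)
  tp <- m[k, k]
  fp <- sum(m[, k]) - tp
  fn <- sum(m[k, ]) - tp
  tn <- total - tp - fp - fn
  p <- if (tp + fp == 0) 0 else tp / (tp + fp)
  r <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  list(tp = tp, tn = tn, fp = fp, fn = fn,
       accuracy = (tp + tn) / total * 100, precision = p, recall = r,
       f_measure = f)
}

toy_table <- function() {
  v <- rbind(
    sleep = c(0.1, 0.2, 0.3),
    wash = c(1, 0, 0),
    dinner = c(0, 1, 0),
    dishes = c(0, 0, 1),
    cook = c(0.5, 0.5, 0)
  )
  embedding_table(v)
}

# A small, fast network configuration for unit tests.
tiny_config <- function(input_dim, embedding_dim, ...) {
  network_config(input_dim = input_dim, embedding_dim = embedding_dim,
                 hidden1 = 8L, epochs = 30L, batch_size = 16L, ...)
}
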