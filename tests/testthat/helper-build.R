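# compact builders for toy studies used across test files

MEDIA_IND_COLS <- c(central_tv = "media_central_tv",
                    local_press = "media_local_press",
                    search_engines = "media_search",
                    social_media = "media_social",
                    influencers = "media_influencers")

ego_row <- function(ego_id = "e1", sex = 1L, age = 50L, education = 9L,
                    single = 0L, employed = 1L, vaccinated = 1L,
                    media = "central_tv") {
  ind <- as.list(setNames(rep(0L, 5), unname(MEDIA_IND_COLS)))
  if (length(media) == 1 && is.na(media)) {
    ind <- as.list(setNames(rep(NA_integer_, 5), unname(MEDIA_IND_COLS)))
  } else if (length(media) > 0) {
    for (m in media) ind[[MEDIA_IND_COLS[[m]]]] <- 1L
  }
  dplyr::bind_cols(
    tibble::tibble(ego_id = ego_id, sex = sex, age = age,
                   education = education, single = single,
                   employed = employed, vaccinated = vaccinated),
    tibble::as_tibble(ind))
}

alter_rows <- function(ego_id = "e1", n = 3, vaccinated = 1L, sex = 0L,
                       age = 40L, education = 9L, single = 0L,
                       closeness = "close", meet = "weekly",
                       ids = sprintf("a%02d", seq_len(n))) {
  tibble::tibble(ego_id = ego_id, alter_id = ids,
                 sex = rep_len(sex, n), age = rep_len(age, n),
                 education = rep_len(education, n),
                 single = rep_len(single, n),
                 vaccinated = rep_len(vaccinated, n),
                 closeness = rep_len(closeness, n),
                 meet_frequency = rep_len(meet, n))
}

tie_rows <- function(ego_id = "e1", pairs = list(),
                     strength = "acquaintance") {
  if (length(pairs) == 0) {
    return(tibble::tibble(ego_id = character(0), a = character(0),
                          b = character(0), strength = character(0)))
  }
  m <- do.call(rbind, pairs)
  tibble::tibble(ego_id = ego_id, a = m[, 1], b = m[, 2],
                 strength = rep_len(strength, nrow(m)))
}

# one-ego study -> personal_network
toy_network <- function(alters, ties, ego = ego_row()) {
  s <- study_data(ego, alters, ties)
  get_network(s, ego$ego_id)
}

# personal network from an adjacency matrix and a vaccination vector
network_from_adj <- function(A, vacc, ego = ego_row()) {
  n <- nrow(A)
  ids <- sprintf("a%02d", seq_len(n))
  pairs <- which(upper.tri(A) & A == 1, arr.ind = TRUE)
  ties <- if (nrow(pairs) == 0) tie_rows(ego$ego_id, list()) else
    tibble::tibble(ego_id = ego$ego_id, a = ids[pairs[, 1]],
                   b = ids[pairs[, 2]], strength = "acquaintance")
  alters <- alter_rows(ego$ego_id, n = n, vaccinated = vacc, ids = ids)
  toy_network(alters, ties, ego = ego)
}

random_adjacency <- function(n, p) {
  A <- matrix(0L, n, n)
  up <- which(upper.tri(A))
  A[up] <- as.integer(runif(length(up)) < p)
  A + t(A)
}

# 25-alter network, 14 vaccinated; focal a01 (vaccinated) has 9 neighbours of
# whom 6 are vaccinated -> neighbor 6/9, overall 13/24, score exactly 1/8
worked_example_network <- function() {
  # a01 vaccinated focal; neighbours a02..a10 (6 vaccinated, 3 not);
  # remaining 15 alters: 7 vaccinated, 8 not (total vaccinated = 14)
  vacc <- c(1, rep(1, 6), rep(0, 3), rep(1, 7), rep(0, 8))
  a <- alter_rows(n = 25, vaccinated = vacc)
  pairs <- lapply(2:10, function(i) c("a01", sprintf("a%02d", i)))
  # tie the non-neighbours together so no alter is an isolate
  others <- sprintf("a%02d", 11:25)
  pairs <- c(pairs,
             lapply(seq_len(14), function(i) c(others[i], others[i + 1])),
             list(c("a02", "a11")))
  toy_network(a, tie_rows(pairs = pairs))
}

zero_coefficients <- function() {
  setNames(as.list(rep(0, 15)),
           names(generator_config(seed = 1)$coefficients))
}
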