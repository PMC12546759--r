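# Condition assembly: ordered prompt construction from one or more clinical
# text reports, a pluggable deterministic text embedder, and concatenation
# with patient-specific scalars into the condition vector
# c = [text embedding | heart rate | age | sex(0/1)].

english_ordinal <- function(n) {
  suffix <- if (n %% 100 %in% 11:13) "th"
  else switch(as.character(n %% 10), "1" = "st", "2" = "nd", "3" = "rd", "th")
  paste0(n, suffix)
}

#' Build the ordered prompt from clinical text reports
#'
#' A single report renders as "The report of the ECG is that {text}.".
#' With several reports the first renders as "Most importantly, The 1st
#' diagnosis is {text}." and each subsequent one as "As a supplementary
#' condition, the 2nd/3rd/... diagnosis is {text}." (English ordinal rules);
#' the pieces are joined by single spaces into one string which is embedded
#' once.
#'
#' @param reports non-empty character vector; entries are whitespace-trimmed
#'   and must be non-empty.
#' @return a single prompt string.
#' @export
build_prompt <- function(reports) {
  reports <- trimws(reports)
  if (!length(reports) || any(!nzchar(reports)))
    stop("reports must be a non-empty list of non-empty strings")
  if (length(reports) == 1L) {
    return(sprintf("The report of the ECG is that %s.", reports))
  }
  parts <- character(length(reports))
  parts[1] <- sprintf("Most importantly, The 1st diagnosis is %s.", reports[1])
  for (i in seq_along(reports)[-1]) {
    parts[i] <- sprintf("As a supplementary condition, the %s diagnosis is %s.",
                        english_ordinal(i), reports[i])
  }
  paste(parts, collapse = " ")
}

#' Encode sex as the indicator used in the condition vector
#'
#' @param sex "F" or "M".
#' @return 0 for F, 1 for M.
#' @export
encode_sex <- function(sex) {
  if (!is.character(sex) || length(sex) != 1L || !sex %in% c("F", "M"))
    stop("sex must be 'F' or 'M'")
  if (sex == "M") 1 else 0
}

# deterministic 31-bit string hash (seed-mixed polynomial rolling hash);
# independent of the R RNG so embedders are reproducible across sessions
.str_hash <- function(s, seed, salt = 0) {
  h <- (as.numeric(seed) * 2654435761 + salt * 40503) %% 2147483647
  for (code in utf8ToInt(s)) h <- (h * 131 + code) %% 2147483647
  h
}

#' Create a deterministic feature-hashing text embedder
#'
#' Offline stand-in for an external semantic embedding service: the prompt is
#' lower-cased and split on non-alphanumerics, each token is hashed (seeded)
#' to a coordinate and a sign, token counts are accumulated, and the result
#' is L2-normalized. Deterministic per (dim, seed); distinct cardiology terms
#' map to non-collinear directions with high probability for dim >= 64.
#'
#' @param dim embedding length (>= 1).
#' @param seed integer mixed into the hash.
#' @return a `text_embedder` list with fields `dim` and `embed(text)`.
#' @export
make_hash_embedder <- function(dim = 64L, seed = 0L) {
  stopifnot(dim >= 1)
  dim <- as.integer(dim)
  embed <- function(text) {
    stopifnot(is.character(text), length(text) == 1L)
    tokens <- strsplit(tolower(text), "[^a-z0-9]+")[[1]]
    tokens <- tokens[nzchar(tokens)]
    v <- numeric(dim)
    for (tk in tokens) {
      idx <- (.str_hash(tk, seed, salt = 1) %% dim) + 1
      sgn <- if (.str_hash(tk, seed, salt = 2) %% 2 == 0) 1 else -1
      v[idx] <- v[idx] + sgn
    }
    nv <- sqrt(sum(v^2))
    if (nv == 0) { v[1] <- 1; nv <- 1 }
    v / nv
  }
  structure(list(dim = dim, embed = embed, kind = "hash", seed = seed),
            class = "text_embedder")
}

#' Assemble the condition vector
#'
#' Concatenates the embedding of the ordered prompt with the three
#' patient-specific entries `[heart rate | age | sex]`. In `"scaled"` mode
#' (default) heart rate and age are divided by 100 to keep them commensurate
#' with a unit-norm text embedding; `"raw"` passes them through unchanged.
#' Sex is always the 0/1 indicator of [encode_sex()].
#'
#' @param reports character vector of report strings.
#' @param patient list with `heart_rate` (bpm, in (0,300)), `age` (0-120),
#'   `sex` ("F"/"M").
#' @param embedder a `text_embedder` (see [make_hash_embedder()]).
#' @param scalars_mode "scaled" or "raw".
#' @return numeric vector of length `embedder$dim + 3`.
#' @export
assemble_condition <- function(reports, patient, embedder,
                               scalars_mode = c("scaled", "raw")) {
  scalars_mode <- match.arg(scalars_mode)
  stopifnot(patient$heart_rate > 0, patient$heart_rate < 300,
            patient$age >= 0, patient$age <= 120)
  emb <- embedder$embed(build_prompt(reports))
  stopifnot(length(emb) == embedder$dim, all(is.finite(emb)))
  s <- if (scalars_mode == "scaled") 1 / 100 else 1
  c(emb, patient$heart_rate * s, patient$age * s, encode_sex(patient$sex))
}

#' Condition matrix for a preprocessed dataset
#'
#' Vectorized [assemble_condition()] over a [preprocess_records()] output.
#' Under the `"no_patient_info"` variant the three scalar slots are omitted
#' and the condition is the text embedding alone.
#'
#' @param ds a [preprocess_records()] result.
#' @param embedder a `text_embedder`.
#' @param scalars_mode "scaled" or "raw".
#' @param patient_info include the three patient-specific entries?
#' @return matrix [cond_dim x N].
#' @export
condition_matrix <- function(ds, embedder, scalars_mode = "scaled",
                             patient_info = TRUE) {
  N <- length(ds$heart_rate)
  dim_out <- embedder$dim + if (patient_info) 3L else 0L
  out <- matrix(0, dim_out, N)
  for (i in seq_len(N)) {
    if (patient_info) {
      out[, i] <- assemble_condition(
        ds$reports[[i]],
        list(heart_rate = ds$heart_rate[i], age = ds$age[i], sex = ds$sex[i]),
        embedder, scalars_mode)
    } else {
      out[, i] <- embedder$embed(build_prompt(ds$reports[[i]]))
    }
  }
  out
}
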