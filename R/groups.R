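#' Enumerate the 20 demographic groups
#'
#' Seven age bands for each sex, plus pregnant and lactating variants for
#' females in the three reproductive-age bands (14-18, 19-30 and 31-50
#' years): 14 + 3 + 3 = 20 groups. The ordering is deterministic: males by
#' age, then females by age, then pregnant, then lactating.
#'
#' @return A data frame with columns `group_id`, `sex` ("male"/"female"),
#'   `age_band` and `reproductive_status` ("none"/"pregnant"/"lactating").
#' @export
enumerate_groups <- function() {
  bands <- age_bands()
  repro_bands <- c("14-18", "19-30", "31-50")
  g <- rbind(
    data.frame(sex = "male", age_band = bands, reproductive_status = "none"),
    data.frame(sex = "female", age_band = bands, reproductive_status = "none"),
    data.frame(sex = "female", age_band = repro_bands,
               reproductive_status = "pregnant"),
    data.frame(sex = "female", age_band = repro_bands,
               reproductive_status = "lactating")
  )
  g$group_id <- paste0(
    ifelse(g$sex == "male", "M", "F"), "_", gsub("\\+", "plus", g$age_band),
    ifelse(g$reproductive_status == "none", "",
           paste0("_", substr(g$reproductive_status, 1, 4)))
  )
  g[, c("group_id", "sex", "age_band", "reproductive_status")]
}

#' @rdname enumerate_groups
#' @export
age_bands <- function() {
  c("4-8", "9-13", "14-18", "19-30", "31-50", "51-70", "71+")
}

validate_groups <- function(groups) {
  stopifnot(nrow(groups) == 20L)
  bad <- groups$reproductive_status != "none" &
    (groups$sex != "female" | !groups$age_band %in% c("14-18", "19-30", "31-50"))
  if (any(bad)) {
    stop("pregnant/lactating status is only valid for females aged 14-50")
  }
  if (anyDuplicated(groups$group_id)) stop("duplicate group_id")
  invisible(groups)
}
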