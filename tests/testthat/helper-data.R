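# small hand-built survey used across tests: 2 species, 4 informants in
# 2 ethnic groups; i4 does not know species A (absent from its locality)
tiny_survey <- function() {
  informants <- tibble::tibble(
    informant_id = c("i1", "i2", "i3", "i4"),
    ethnic_group = c("Mokolé", "Mokolé", "Zerma", "Zerma"),
    municipality = c("Kandi", "Kandi", "Malanville", "Malanville"),
    zone = c("Sudanian", "Sudanian", "Sudanian", "Sudanian"),
    sex = c("f", "m", "f", "m"),
    age = c(40L, 55L, 33L, 61L),
    occupation = c("farmer", "healer", "powder seller", "farmer")
  )
  use_reports <- tibble::tibble(
    informant_id = c("i1", "i1", "i1", "i2", "i3", "i3"),
    species = c("sp_A", "sp_A", "sp_B", "sp_A", "sp_A", "sp_B"),
    organ = c("rootstock", "leaf", "rootstock", "rootstock", "rootstock",
              "stem bark"),
    category = c("medicinal", "food", "medicinal", "dye", "medicinal",
                 "handicraft"),
    specific_use = c("jaundice remedy", "sauce ingredient", "jaundice remedy",
                     "butter colouring", "malaria remedy", "rope"),
    affection_category = c("liver", NA, "liver", NA, "infectious", NA)
  )
  responses <- tibble::tibble(
    informant_id = rep(c("i1", "i2", "i3", "i4"), each = 2),
    species = rep(c("sp_A", "sp_B"), 4),
    sells = c(TRUE, FALSE, FALSE, NA, TRUE, TRUE, NA, FALSE),
    perceived_dynamic = c("decrease", "stable", "decrease", NA, "decrease",
                          "decrease", NA, "stable"),
    harvest_tool = c("axe", NA, "hoe", NA, "axe", "machete", NA, NA),
    conservation_practice = c("partial harvest", "none", "none", NA, "none",
                              "none", NA, "none"),
    knows_species = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, TRUE)
  )
  interview_set(informants, use_reports, responses)
}

extdata <- function(name) {
  system.file("extdata", name, package = "usevalue", mustWork = TRUE)
}

table_body <- function(tab) tab[tab$row_type == "group", ]

# group-level UV and Ni maps from a packaged table
table_maps <- function(tab) {
  body <- table_body(tab)
  list(uv = stats::setNames(body$UV, body$ethnic_group),
       ni = stats::setNames(body$Ni, body$ethnic_group))
}
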