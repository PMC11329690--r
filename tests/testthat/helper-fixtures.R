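# Small in-code fixtures shared across tests.

tiny_registry <- function() {
  data.frame(food_id = c("a", "b", "c"),
             name = c("apple", "beef cut", "cheese"),
             food_group = c("Fruit and vegetables", "Beef", "Solid dairy"),
             stringsAsFactors = FALSE)
}

tiny_intakes <- function() {
  data.frame(person_id = c("p1", "p2"),
             a = c(100, 50), b = c(20, 80), c = c(30, 10),
             stringsAsFactors = FALSE)
}

tiny_factors <- function() {
  data.frame(food_id = c("a", "b", "c"),
             gwp = c(0.001, 0.030, 0.010),
             land_use = c(0.002, 0.040, 0.009),
             marine_eutroph = c(1e-6, 30e-6, 12e-6),
             freshwater_eutroph = c(0.3e-6, 4e-6, 2.5e-6),
             origin_flag = "domestic", adapted = FALSE,
             stringsAsFactors = FALSE)
}

tiny_persons <- function() {
  data.frame(person_id = c("p1", "p2"),
             sex = c("female", "male"), age = c(40, 60),
             education = c(2L, 3L), income = c(5L, 7L),
             municipality = c("urban", "rural"), smoking = c(1L, 4L),
             physical_activity = c(2L, 3L), bmi = c(24, 28),
             waist = c(80, 100), survey_weight = c(1.2, 0.8),
             stringsAsFactors = FALSE)
}

write_temp_csv <- function(df) {
  f <- tempfile(fileext = ".csv")
  utils::write.csv(df, f, row.names = FALSE)
  f
}

small_spec <- function(n = 200, seed = 11, ...) {
  population_spec(n_persons = n, seed = seed, ...)
}
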