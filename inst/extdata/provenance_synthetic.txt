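Synthetic / placeholder inputs (not published values):
  response.p_resp_wk24_dup                                [figure-only-placeholder] = 0.6
  response.p_resp_wk24_bsc                                [figure-only-placeholder] = 0.25
  response.p_resp_wk52_given_wk24_dup                     [figure-only-placeholder] = 0.9
  response.p_resp_wk52_given_wk24_bsc                     [figure-only-placeholder] = 0.65
  drug_cost.price_per_administration                      [synthetic] = 580
  indirect.workdays_lost_per_year_by_state.controlled     [synthetic] = 1
  indirect.workdays_lost_per_year_by_state.inadequate     [synthetic] = 6
  indirect.workdays_lost_per_year_by_state.surgery        [synthetic] = 10
  indirect.workdays_lost_per_year_by_state.postop_controlled [synthetic] = 1
  indirect.workdays_lost_per_year_by_state.postop_uncontrolled [synthetic] = 6
  indirect.workdays_lost_per_year_by_state.death          [synthetic] = 0
  life_table.makeham_a                                    [synthetic] = 5e-04
  life_table.gompertz_b                                   [synthetic] = 2.5e-05
  life_table.gompertz_c                                   [synthetic] = 0.09
  life_table.min_age                                      [synthetic] = 0
  life_table.max_age                                      [synthetic] = 110
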