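# Placeholder model configuration for the soilwheat simulator.
#
# NON-AUTHORITATIVE: apart from the growth parameters and total soil
# concentrations (field-survey scale values), every entry below is a
# documented placeholder. Partition coefficients and soil mass act as
# effective calibration constants (the accumulation equation is applied
# verbatim, so they absorb its unit bookkeeping); they were chosen once so
# that the simulated tissue concentrations reproduce the qualitative
# ordering root > leaf > stem, grain for all four metals. Replace them with
# site-specific or literature values for any quantitative use.
#
# Every numeric parameter carries {value, unit, source}; the loader rejects
# unknown keys and unit mismatches.

simulation:
  t_end:           {value: 160,  unit: d, source: growing-season horizon}
  dt:              {value: 0.5,  unit: d, source: placeholder}
  tau:             {value: 1,    unit: d, source: placeholder}
  grain_emergence: {value: 50,   unit: d, source: field survey}
  integrator: rk4

growth:
  root:
    m0:   {value: 0.0025,    unit: kg,  source: field survey}
    mmax: {value: 0.25,      unit: kg,  source: field survey}
    g:    {value: 0.0075,    unit: 1/d, source: literature}
    emergence_day: {value: 0, unit: d,  source: field survey}
  stem:
    m0:   {value: 0.00125,   unit: kg,  source: field survey}
    mmax: {value: 0.45,      unit: kg,  source: field survey}
    g:    {value: 0.08,      unit: 1/d, source: literature}
    emergence_day: {value: 0, unit: d,  source: field survey}
  leaf:
    m0:   {value: 0.00125,   unit: kg,  source: field survey}
    mmax: {value: 0.05,      unit: kg,  source: field survey}
    g:    {value: 0.08,      unit: 1/d, source: literature}
    emergence_day: {value: 0, unit: d,  source: field survey}
  grain:
    m0:   {value: 5.6e-6,    unit: kg,  source: field survey}
    mmax: {value: 0.56,      unit: kg,  source: field survey}
    g:    {value: 0.14,      unit: 1/d, source: literature}
    emergence_day: {value: 50, unit: d, source: field survey}

geometry:
  root:
    area:          {value: 0.05,  unit: m2,   source: placeholder}
    water_content: {value: 0.8,   unit: L/kg, source: placeholder}
  stem:
    area:          {value: 0.02,  unit: m2,   source: placeholder}
    water_content: {value: 0.6,   unit: L/kg, source: placeholder}
  leaf:
    area:          {value: 0.06,  unit: m2,   source: placeholder}
    water_content: {value: 0.7,   unit: L/kg, source: placeholder}
    permeability:  {value: 1.0e-4, unit: m/d, source: placeholder}
  grain:
    area:          {value: 2.0e-4, unit: m2,  source: placeholder}
    water_content: {value: 0.12,  unit: L/kg, source: placeholder}
    permeability:  {value: 5.0e-5, unit: m/d, source: placeholder}

atmosphere:
  f_p:   {value: 0.5,  unit: "-",  source: placeholder}
  v_dep: {value: 17.3, unit: m/d,  source: placeholder}

root_transport:
  q:   {value: 2,      unit: L/d,  source: placeholder}
  f_c: {value: 1000,   unit: L/m3, source: placeholder}
  d_r: {value: 1.0e-5, unit: m/d,  source: placeholder}

soil:
  m_s: {value: 2, unit: kg, source: placeholder}

flux:
  q_up:
    root:  {value: 2,      unit: L/(kg d), source: placeholder}
    stem:  {value: 2,      unit: L/(kg d), source: placeholder}
    leaf:  {value: 1,      unit: L/(kg d), source: placeholder}
    grain: {value: 2.3e-4, unit: L/(kg d), source: placeholder}
  phloem_fraction:
    root:  {value: 0.2, unit: "-", source: placeholder}
    stem:  {value: 0.3, unit: "-", source: placeholder}
    leaf:  {value: 0.3, unit: "-", source: placeholder}
    grain: {value: 0.0, unit: "-", source: placeholder}

metals:
  Cu:
    c_total: {value: 22.1,   unit: mg/kg, source: field survey}
    c_s:     {value: 1.105,  unit: mg/L,  source: placeholder}
    c_t:     {value: 2.21,   unit: mg/L,  source: placeholder}
    c_a:     {value: 5.0e-5, unit: mg/m3, source: placeholder}
    k_sw:    {value: 9.5,    unit: L/kg,  source: placeholder}
    k_iw:
      root:  {value: 0.94, unit: L/kg, source: placeholder}
      stem:  {value: 5.0,  unit: L/kg, source: placeholder}
      leaf:  {value: 1.75, unit: L/kg, source: placeholder}
      grain: {value: 100,  unit: L/kg, source: placeholder}
  Cd:
    c_total: {value: 0.6,    unit: mg/kg, source: field survey}
    c_s:     {value: 0.03,   unit: mg/L,  source: placeholder}
    c_t:     {value: 0.06,   unit: mg/L,  source: placeholder}
    c_a:     {value: 2.0e-6, unit: mg/m3, source: placeholder}
    k_sw:    {value: 5.8,    unit: L/kg,  source: placeholder}
    k_iw:
      root:  {value: 0.94, unit: L/kg, source: placeholder}
      stem:  {value: 6.7,  unit: L/kg, source: placeholder}
      leaf:  {value: 3.74, unit: L/kg, source: placeholder}
      grain: {value: 100,  unit: L/kg, source: placeholder}
  Pb:
    c_total: {value: 36.3,   unit: mg/kg, source: field survey}
    c_s:     {value: 1.815,  unit: mg/L,  source: placeholder}
    c_t:     {value: 3.63,   unit: mg/L,  source: placeholder}
    c_a:     {value: 1.0e-4, unit: mg/m3, source: placeholder}
    k_sw:    {value: 15.5,   unit: L/kg,  source: placeholder}
    k_iw:
      root:  {value: 0.94, unit: L/kg, source: placeholder}
      stem:  {value: 2.0,  unit: L/kg, source: placeholder}
      leaf:  {value: 0.86, unit: L/kg, source: placeholder}
      grain: {value: 100,  unit: L/kg, source: placeholder}
  Ni:
    c_total: {value: 28.9,   unit: mg/kg, source: field survey}
    c_s:     {value: 1.445,  unit: mg/L,  source: placeholder}
    c_t:     {value: 2.89,   unit: mg/L,  source: placeholder}
    c_a:     {value: 2.0e-5, unit: mg/m3, source: placeholder}
    k_sw:    {value: 22.0,   unit: L/kg,  source: placeholder}
    k_iw:
      root:  {value: 0.94, unit: L/kg, source: placeholder}
      stem:  {value: 7.1,  unit: L/kg, source: placeholder}
      leaf:  {value: 2.47, unit: L/kg, source: placeholder}
      grain: {value: 100,  unit: L/kg, source: placeholder}
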