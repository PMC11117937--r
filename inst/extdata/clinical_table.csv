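# Clinical parameters of the 17 ventilated infants (printed cohort table).
# rss = FiO2% x MAP / 100, printed at 1 decimal.
patient_id,ga_weeks,pma_weeks,fio2_pct,map,rss
p-1,26.3,54.7,30,28,8.4
p-2,35.0,49.9,21,10,2.1
p-3,24.6,57.0,48,20,9.6
p-4,27.9,47.4,25,14,3.5
p-5,28.7,44.1,45,16,7.2
p-6,24.9,53.7,38,13,4.9
p-7,27.4,48.6,36,17,6.1
p-8,24.7,62.4,32,19,6.1
p-9,25.3,51.4,64,21,13.4
p-10,25.0,37.1,45,18,8.1
p-11,27.7,44.4,35,17,6.0
p-12,27.4,56.6,79,20,15.8
p-13,38.3,43.4,24,9,2.2
p-14,28.4,68.1,100,29,29.0
p-15,25.3,59.4,26,22,5.7
p-16,29.0,59.9,24,15,3.6
p-17,23.4,49.0,58,24,13.9
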