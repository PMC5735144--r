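system,charge_model,scheme,entropy_method,window,e_ele,e_vdw,e_internal,g_sol,minus_t_delta_s,g_bind_published
1C5T,AMBER,single,external_nmode,2-4ns,-20.70,-22.97,0.00,6.30,15.62,-21.75
1C5T,AMBER,triple,external_nmode,2-4ns,-51.83,-13.95,-11.28,55.27,11.17,-10.62
1C5T,PPC,single,external_nmode,2-4ns,-28.06,-20.63,0.00,8.09,16.41,-24.19
1C5T,PPC,triple,external_nmode,2-4ns,-15.35,-33.65,-14.10,18.48,22.07,-22.55
1O2J,AMBER,single,external_nmode,2-4ns,-8.87,-31.61,0.00,1.93,20.78,-17.77
1O2J,AMBER,triple,external_nmode,2-4ns,-29.54,-48.07,2.64,40.34,27.69,-6.94
1O2J,PPC,single,external_nmode,2-4ns,-33.40,-32.05,0.00,22.12,21.59,-21.74
1O2J,PPC,triple,external_nmode,2-4ns,42.85,-31.11,-11.69,-36.51,18.14,-18.32
1C5T,AMBER,single,external_nmode,80-90ns,-44.19,0.00,0.00,8.34,19.58,-16.27
1C5T,AMBER,single,IE,80-90ns,-44.19,0.00,0.00,8.34,27.62,-8.23
1C5T,PPC,single,external_nmode,80-90ns,-53.05,0.00,0.00,15.18,17.28,-20.59
1C5T,PPC,single,IE,80-90ns,-53.05,0.00,0.00,15.18,29.99,-7.88
1O2J,AMBER,single,external_nmode,80-90ns,-47.04,0.00,0.00,10.61,18.20,-18.23
1O2J,AMBER,single,IE,80-90ns,-47.04,0.00,0.00,10.61,34.86,-1.57
1O2J,PPC,single,external_nmode,80-90ns,-55.56,0.00,0.00,15.76,20.73,-19.07
1O2J,PPC,single,IE,80-90ns,-55.56,0.00,0.00,15.76,34.15,-5.65
1C5T,AMBER,single,external_nmode,80-90ns-group,-22.36,-21.83,0.00,8.34,19.58,-16.27
1C5T,AMBER,triple,external_nmode,80-90ns-group,-35.74,-20.63,-17.57,14.27,16.04,-43.63
1O2J,AMBER,single,external_nmode,80-90ns-group,-15.22,-31.82,0.00,10.61,18.20,-18.23
1O2J,AMBER,triple,external_nmode,80-90ns-group,127.65,-22.19,-7.51,-166.82,18.77,-50.10
1C5T,PPC,single,external_nmode,80-90ns-group,-32.05,-21.00,0.00,15.18,17.28,-20.59
1C5T,PPC,triple,external_nmode,80-90ns-group,79.59,-43.66,-13.28,-42.09,21.58,2.14
1O2J,PPC,single,external_nmode,80-90ns-group,-27.24,-28.32,0.00,15.76,20.73,-19.07
1O2J,PPC,triple,external_nmode,80-90ns-group,-58.16,-16.21,-19.55,25.25,22.17,-46.50
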