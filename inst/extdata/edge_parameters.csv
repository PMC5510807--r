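patient,edge,n_beads,cbf_hz,cba_um,lambda_um,rho_c_pct,h_um,uw_um_s,tau_w_mpa
1,1,8,14.0,7.5,13.0,84,87.5,138.3,3.2
1,2,4,15.0,6.8,14.6,86,52.6,240.9,9.2
1,3,5,13.5,7.5,19.8,89,47.4,224.8,9.5
1,4,5,13.6,4.0,28.0,82,70.9,49.4,1.4
2,1,3,5.3,7.0,10.8,73,7.0,27.6,0.7
2,2,3,5.6,6.6,11.3,80,32.9,46.9,2.9
2,3,9,6.3,7.3,11.0,68,28.9,55.2,3.8
3,1,6,14.0,5.4,10.5,69,53.0,51.3,1.9
4,1,4,11.5,7.5,12.0,74,66.3,76.8,2.3
5,1,3,7.3,7.8,16.0,58,82.1,24.0,0.6
5,2,3,9.4,7.0,15.5,80,91.5,80.1,1.8
5,3,3,4.9,8.4,17.3,88,53.5,64.7,2.4
5,4,4,5.6,6.9,13.3,95,52.8,106.5,4.0
5,5,3,8.1,6.7,15.4,82,139.7,85.4,1.2
6,1,4,3.7,6.2,16.7,89,34.2,33.6,2.0
7,1,4,7.7,7.2,12.0,70,42.6,49.3,2.3
8,1,3,3.6,6.3,17.7,98,40.1,32.3,1.6
9,1,12,7.7,8.8,12.1,62,60.0,51.7,1.7
9,2,5,6.6,7.0,10.3,73,52.3,54.4,2.1
10,1,3,6.7,6.5,10.4,87,28.6,60.2,4.2
11,1,56,3.6,4.7,10.2,96,51.2,58.9,2.3
11,2,11,3.5,5.3,12.6,89,48.6,45.6,1.9
11,3,6,4.9,4.8,18.5,89,50.5,44.3,1.8
11,4,28,6.0,5.2,16.7,86,45.4,56.4,2.5
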