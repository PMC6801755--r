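# package: kinesim 0.1.0
# description: synthetic force-velocity data, DmK parameters, 2% multiplicative noise
# generator: generate_synthetic_fv
# noise_cv: 0.02
# seed: 20
force_pN,velocity_nm_s,sigma_nm_s
-5,796.6952205474877,15.571802301521739
-4.107142857142857,769.0073947744796,15.562517085717605
-3.2142857142857144,804.88798000473,15.542739260006273
-2.321428571428571,754.3787659125034,15.50069797072848
-1.4285714285714284,763.7036043146709,15.411719319564693
-0.5357142857142856,769.9283218334012,15.225120005289886
0.35714285714285765,699.1740821395351,14.841220360705336
1.25,691.8438129585084,14.081619980506444
2.1428571428571432,628.5568901734795,12.688302267499958
3.0357142857142865,516.9411185539019,10.454985817812064
3.928571428571429,377.245310019147,7.547945813692591
4.821428571428571,231.2958810076224,4.639872707702298
5.714285714285715,118.70767278685086,2.4043582912038253
6.607142857142858,51.787732304188445,1.0090507073512733
7.5,12.030713237039292,0.24816518979997224
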