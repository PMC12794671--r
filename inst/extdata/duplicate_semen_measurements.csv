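sample,method,metric,m1,m2
1,casa,concentration,156.6,147.1
1,model,concentration,151.5,149.1
1,casa,npim,41.4,54.4
1,model,npim,39.6,48.7
1,casa,slow,6.9,11.8
1,model,slow,19.6,21.8
1,casa,rapid,51.7,33.8
1,model,rapid,40.8,29.5
2,casa,concentration,47.3,47.1
2,model,concentration,41.2,46.4
2,casa,npim,79.9,74.2
2,model,npim,74.7,67.1
2,casa,slow,6.5,7.6
2,model,slow,14.7,17.2
2,casa,rapid,13.5,18.3
2,model,rapid,10.6,15.7
3,casa,concentration,13.2,22.9
3,model,concentration,29.4,32.1
3,casa,npim,70.6,78.0
3,model,npim,84.8,84.0
3,casa,slow,12.2,10
3,model,slow,11.3,12.4
3,casa,rapid,17.1,11.9
3,model,rapid,3.9,3.6
4,casa,concentration,40.4,41.9
4,model,concentration,38.4,41.8
4,casa,npim,93.3,94
4,model,npim,93.4,92.4
4,casa,slow,4.4,2.9
4,model,slow,6.1,6.6
4,casa,rapid,2.3,3.2
4,model,rapid,0.5,1.0
5,casa,concentration,203.7,339.8
5,model,concentration,216.7,241.8
5,casa,npim,81.8,85.2
5,model,npim,80.3,81.6
5,casa,slow,6.4,5.9
5,model,slow,15.4,14.9
5,casa,rapid,11.8,8.9
5,model,rapid,4.3,3.5
6,casa,concentration,9.1,8.4
6,model,concentration,8.7,8.4
6,casa,npim,91.8,91.8
6,model,npim,92.4,93.4
6,casa,slow,5.1,3.8
6,model,slow,4.7,4.1
6,casa,rapid,3.1,4.3
6,model,rapid,2.9,2.5
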