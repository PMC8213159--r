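type,freq,state,current_pA,mu,sigma,min,max
PKCd,LF,X,120,2,0.5,1,3
PKCd,LF,X,140,3,0.75,1.5,4.5
PKCd,LF,X,160,4,1,2,6
PKCd,LF,X,180,5,1.25,2.5,7.5
PKCd,LF,X,200,6,1.5,3,9
PKCd,LF,X,220,7,1.75,3.5,10.5
PKCd,LF,Y,120,3.5,0.875,1.75,5.25
PKCd,LF,Y,140,5,1.25,2.5,7.5
PKCd,LF,Y,160,6.5,1.625,3.25,9.75
PKCd,LF,Y,180,8,2,4,12
PKCd,LF,Y,200,9.5,2.375,4.75,14.25
PKCd,LF,Y,220,11,2.75,5.5,16.5
PKCd,RS,X,120,4,1,2,6
PKCd,RS,X,140,6,1.5,3,9
PKCd,RS,X,160,8,2,4,12
PKCd,RS,X,180,10,2.5,5,15
PKCd,RS,X,200,12,3,6,18
PKCd,RS,X,220,14,3.5,7,21
PKCd,RS,Y,120,6.5,1.625,3.25,9.75
PKCd,RS,Y,140,9.5,2.375,4.75,14.25
PKCd,RS,Y,160,12.5,3.125,6.25,18.75
PKCd,RS,Y,180,15.5,3.875,7.75,23.25
PKCd,RS,Y,200,18.5,4.625,9.25,27.75
PKCd,RS,Y,220,21.5,5.375,10.75,32.25
SOM,LF,X,120,5,1.25,2.5,7.5
SOM,LF,X,140,7,1.75,3.5,10.5
SOM,LF,X,160,9,2.25,4.5,13.5
SOM,LF,X,180,11,2.75,5.5,16.5
SOM,LF,X,200,13,3.25,6.5,19.5
SOM,LF,X,220,15,3.75,7.5,22.5
SOM,LF,Y,120,3,0.75,1.5,4.5
SOM,LF,Y,140,4.5,1.125,2.25,6.75
SOM,LF,Y,160,6,1.5,3,9
SOM,LF,Y,180,7.5,1.875,3.75,11.25
SOM,LF,Y,200,9,2.25,4.5,13.5
SOM,LF,Y,220,10.5,2.625,5.25,15.75
SOM,RS,X,120,8,2,4,12
SOM,RS,X,140,11,2.75,5.5,16.5
SOM,RS,X,160,14,3.5,7,21
SOM,RS,X,180,17,4.25,8.5,25.5
SOM,RS,X,200,20,5,10,30
SOM,RS,X,220,23,5.75,11.5,34.5
SOM,RS,Y,120,6,1.5,3,9
SOM,RS,Y,140,8.5,2.125,4.25,12.75
SOM,RS,Y,160,11,2.75,5.5,16.5
SOM,RS,Y,180,13.5,3.375,6.75,20.25
SOM,RS,Y,200,16,4,8,24
SOM,RS,Y,220,18.5,4.625,9.25,27.75
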