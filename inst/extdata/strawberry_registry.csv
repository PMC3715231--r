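"name","formula","mw","group","n_C","n_H","n_O","n_carbonyl","n_ether","n_methyl","thresholds","descriptors","is_standard"
"Methyl acetate","C3H6O2",74.079,"ester",3,6,2,1,1,2,"6169.88@backsolved","etherial;sweet",FALSE
"Ethyl acetate","C4H8O2",88.106,"ester",4,8,2,1,1,2,"2630.97@backsolved","sweet fruit;grape;fruity;pineapple",FALSE
"Methyl propionate","C4H8O2",88.106,"ester",4,8,2,1,1,2,"98.0769@backsolved","",FALSE
"S-Methyl thioacetate","C3H6OS",90.14,"ester",3,6,1,1,0,2,"1.60821@backsolved","sulfurous;cheesy",FALSE
"Isopropyl acetate","C5H10O2",102.133,"ester",5,10,2,1,1,3,"2640@backsolved","",FALSE
"Ethyl propionate","C5H10O2",102.133,"ester",5,10,2,1,1,2,"6.99346@backsolved","",FALSE
"Propyl acetate","C5H10O2",102.133,"ester",5,10,2,1,1,2,"973.684@backsolved","",FALSE
"Methyl butyrate","C5H10O2",102.133,"ester",5,10,2,1,1,2,"7.09744@backsolved","apple;fruity;cheese",FALSE
"Methyl 2-methylbutanoate","C6H12O2",116.16,"ester",6,12,2,1,1,3,"0.1@backsolved","green apple;fruity;sweet",FALSE
"Isobutyl acetate","C6H12O2",116.16,"ester",6,12,2,1,1,3,"479.381@backsolved","strawberry;light fruity;flowery",FALSE
"Methyl isovalerate","C6H12O2",116.16,"ester",6,12,2,1,1,3,"2.19691@backsolved","fruity;apple;pineapple",FALSE
"Ethyl butyrate","C6H12O2",116.16,"ester",6,12,2,1,1,2,"0.249513@backsolved","fruity;sweet;pineapple;strawberry;cheese",FALSE
"Butyl acetate","C6H12O2",116.16,"ester",6,12,2,1,1,2,"192.105@backsolved","fruity;banana;apple;glue",TRUE
"Isopropyl butyrate","C7H14O2",130.187,"ester",7,14,2,1,1,3,"6.20202@backsolved","fruity;sweet;pineapple",FALSE
"Ethyl 2-methylbutyrate","C7H14O2",130.187,"ester",7,14,2,1,1,3,"0.0667674@backsolved","sour;cheesy;sweaty;fruity",FALSE
"Ethyl isovalerate","C7H14O2",130.187,"ester",7,14,2,1,1,3,"0.089196@backsolved","fruity;apple;pineapple;sweet fruit",FALSE
"Isoamyl acetate","C7H14O2",130.187,"ester",7,14,2,1,1,3,"3.7931@backsolved","",FALSE
"Ethyl valerate","C7H14O2",130.187,"ester",7,14,2,1,1,2,"0.33379@backsolved","",FALSE
"Methyl hexanoate","C7H14O2",130.187,"ester",7,14,2,1,1,2,"15.5814@backsolved","fruity;pineapple;ester-like",FALSE
"trans-2-Hexenyl acetate","C8H14O2",142.198,"ester",8,14,2,1,1,2,"42.8889@backsolved","",FALSE
"Ethyl hexanoate","C8H16O2",144.214,"ester",8,16,2,1,1,2,"0.200942@backsolved","fruity;sweet;pineapple;green apple",FALSE
"Hexyl acetate","C8H16O2",144.214,"ester",8,16,2,1,1,2,"2.01097@backsolved","fruity;green apple;banana;pear",FALSE
"Methyl octanoate","C9H18O2",158.241,"ester",9,18,2,1,1,2,"36.5@backsolved","sweet fruity",FALSE
"Ethyl alcohol","C2H6O",46.069,"alcohol",2,6,1,0,0,1,"28807.7@backsolved","",FALSE
"Isopropyl alcohol","C3H8O",60.096,"alcohol",3,8,1,0,0,2,"25994.4@backsolved","fruity",FALSE
"n-Propyl alcohol","C3H8O",60.096,"alcohol",3,8,1,0,0,1,"2330@backsolved","sweet (candy)",FALSE
"Isobutyl alcohol","C4H10O",74.123,"alcohol",4,10,1,0,0,2,"834.526@backsolved","plastic;bad",TRUE
"Isopropenylethyl alcohol","C5H10O",86.134,"alcohol",5,10,1,0,0,1,"2497.21@backsolved","",FALSE
"3-Methyl-1-butanol","C5H12O",88.15,"alcohol",5,12,1,0,0,2,"44.8673@backsolved","bitter;harsh;alcoholic;fusel oil",FALSE
"2-Methyl-1-butanol","C5H12O",88.15,"alcohol",5,12,1,0,0,2,"40.8333@backsolved","alcoholic;green;fusel oil",FALSE
"n-Pentanol","C5H12O",88.15,"alcohol",5,12,1,0,0,1,"466.981@backsolved","",FALSE
"1-Chloro-2-propanol","C3H7ClO",94.541,"alcohol",3,7,1,0,0,1,"1003.75@backsolved","",FALSE
"n-Hexanol","C6H14O",102.177,"alcohol",6,14,1,0,0,1,"43.4783@backsolved","winey-fruity;green;grass;fresh",FALSE
"Linalool","C10H18O",154.253,"alcohol",10,18,1,0,0,3,"0.187591@backsolved","citrus;floral;sweet;rose",FALSE
"Acetaldehyde","C2H4O",44.053,"aldehyde",2,4,1,1,0,1,"186.011@backsolved","green apple;fruity;pungent",TRUE
"Acrolein","C3H4O",56.064,"aldehyde",3,4,1,1,0,0,"172.5@backsolved","",FALSE
"Methacrolein","C4H6O",70.091,"aldehyde",4,6,1,1,0,1,"8.53846@backsolved","",FALSE
"Isobutyraldehyde","C4H8O",72.107,"aldehyde",4,8,1,1,0,2,"42.2222@backsolved","green;malty;floral",FALSE
"Isovaleraldehyde","C5H10O",86.134,"aldehyde",5,10,1,1,0,2,"2.24771@backsolved","green;malty",TRUE
"Acetone","C3H6O",58.08,"ketone",3,6,1,1,0,2,"41947.6@backsolved","aldehydic;wood pulp;hay",FALSE
"Methyl ethyl ketone","C4H8O",72.107,"ketone",4,8,1,1,0,2,"7803.47@backsolved","butter;sweet;butterscotch",TRUE
"Methyl n-propyl ketone","C5H10O",86.134,"ketone",5,10,1,1,0,2,"1800@backsolved","thinner;acetone;sweet;fruity",FALSE
"Methyl isobutyl ketone","C6H12O",100.161,"ketone",6,12,1,1,0,3,"538.835@backsolved","",TRUE
"Methyl amyl ketone","C7H14O",114.188,"ketone",7,14,1,1,0,2,"140.553@backsolved","meaty;cheese;green",FALSE
"Acetic acid","C2H4O2",60.052,"fatty_acid",2,4,2,1,0,1,"145.02@backsolved","sour;vinegar",FALSE
"2-Propynoic acid","C3H2O2",70.047,"fatty_acid",3,2,2,1,0,0,"94.0541@backsolved","",FALSE
"n-Pentane","C5H12",72.151,"etc",5,12,0,0,0,2,"31510.4@backsolved","",FALSE
"Ethyl ether","C4H10O",74.123,"etc",4,10,1,0,1,2,"330.296@backsolved","",FALSE
"1,3-Hexadiene","C6H10",82.146,"etc",6,10,0,0,0,1,"1997.74@backsolved","",FALSE
"n-Hexane","C6H14",86.178,"etc",6,14,0,0,0,2,"21880.1@backsolved","",FALSE
"Toluene","C7H8",92.141,"etc",7,8,0,0,0,1,"1550@backsolved","",TRUE
"Styrene","C8H8",104.152,"etc",8,8,0,0,0,0,"35.2727@backsolved","",TRUE
"Mesifurane (2,5-dimethyl-4-methoxy-3(2H)-furanone)","C7H10O3",142.154,"etc",7,10,3,1,2,3,"3.27@backsolved","sweet;caramel",FALSE
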