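coat_type,subcategory,image_count,daily_events,percent_images,individuals,images_with_white,camera_sites
solid_black,,9706,8276,40.32,NA,150,478
blotched_brown,,3636,3009,15.10,194,38,281
mackerel_brown,,7413,6011,30.79,349,41,455
mackerel_brown,broken_brown,4266,3545,17.72,204,33,349
mackerel_brown,spotted_brown,2878,2264,11.95,129,8,225
mackerel_brown,striped_brown,224,167,0.93,11,0,19
mackerel_brown,ticked_brown,45,35,0.19,5,0,12
blotched_orange,,297,250,1.23,20,14,46
mackerel_orange,,761,492,3.16,45,8,87
mackerel_orange,broken_orange,457,252,1.90,29,8,62
mackerel_orange,spotted_orange,288,229,1.20,12,0,22
mackerel_orange,striped_orange,7,6,0.03,3,0,3
mackerel_orange,ticked_orange,9,5,0.04,1,0,1
tortoiseshell,,691,508,2.87,55,14,92
tuxedo,,183,160,0.76,11,183,12
unknown,,1388,1014,5.77,NA,0,464
total,,24075,19837,100.00,674,456,651
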